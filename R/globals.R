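# data.table non-standard-evaluation columns
utils::globalVariables(c(
  "patient_id", "date", "encounter_class", "code_type", "code",
  "n_visits", "TotalEDInpatientVisits", "TotalPrednisoneRx", ":="
))
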
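# Default de-identification binning schemes.
# Edges for income, insurance, PM2.5, ozone and roadway distance follow the
# published bin boundaries; closure is first-interval-closed, then (a, b],
# except roadway distance which uses integer half-open [a, a+50) bins.
identifiers:
  - patient_id
  - birth_date
  - date
  - x_m
  - y_m
  - geocode
  - blockgroup_id
schemes:
  - feature: Sex
    strategy: categorical_passthrough
    levels: [male, female, other/missing]
  - feature: Race
    strategy: categorical_passthrough
    levels:
      - Caucasian
      - African American
      - Asian
      - American/Alaskan Native
      - Native Hawaiian/Pacific Islander
      - Unknown/other
  - feature: Ethnicity
    strategy: categorical_passthrough
    levels: [Hispanic, Not Hispanic, Unknown]
  - feature: ResidentialDensity
    strategy: categorical_passthrough
    levels: [rural, urban cluster, urbanized]
  - feature: ProbNoInsurance
    strategy: explicit_edges
    closure: first_closed
    edges: [0.0, 0.0637, 0.1121, 0.1644, 0.5548]
    labels:
      - "[0, 0.0637]"
      - "(0.0637, 0.1121]"
      - "(0.1121, 0.1644]"
      - "(0.1644, 0.5548]"
  - feature: MedianIncome
    strategy: explicit_edges
    closure: first_closed
    edges: [7470, 36635, 46750, 59566, 78355, 250001]
    labels:
      - "[7470, 36635]"
      - "(36635, 46750]"
      - "(46750, 59566]"
      - "(59566, 78355]"
      - "(78355, 250001]"
  - feature: RoadwayDistance
    strategy: explicit_edges
    closure: left_closed
    edges: [0, 50, 100, 150, 200, 250, Inf]
    labels: ["0-49", "50-99", "100-149", "150-199", "200-249", ">=250"]
  - feature: AvgDailyPM25
    strategy: explicit_edges
    closure: first_closed
    edges: [3.27, 6.30, 7.81, 10.83]
    labels:
      - "[3.27, 6.30]"
      - "(6.30, 7.81]"
      - "(7.81, 10.83]"
  - feature: MaxDailyOzone
    strategy: explicit_edges
    closure: first_closed
    edges: [27.80, 39.00, 42.73, 46.45]
    labels:
      - "[27.80, 39.00]"
      - "(39.00, 42.73]"
      - "(42.73, 46.45]"
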
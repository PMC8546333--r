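# Synthetic reporting-system demo: four biologic agents for rheumatoid
# arthritis screened against cardiotoxicity preferred terms, with one
# injected association (adalimumab, RR = 3).
n_reports: 20000
seed: 42
duplicate_rate: 0.10
missing_rate: 0.15
date_range: ["2004-01-01", "2020-09-30"]
drugs:
  - id: abatacept
    synonyms: [abatacept, Orencia]
    p_use: 0.010
  - id: adalimumab
    synonyms: [adalimumab, Humira]
    p_use: 0.060
  - id: tocilizumab
    synonyms: [tocilizumab, Actemra, RoActemra]
    p_use: 0.008
  - id: etanercept
    synonyms: [etanercept, Enbrel]
    p_use: 0.035
events:
  - term: Cardiac failure
    p: 0.012
  - term: Cardiac failure congestive
    p: 0.006
  - term: Cardiomyopathy
    p: 0.003
associations:
  - drug_id: adalimumab
    event: Cardiac failure
    rr: 3.0
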
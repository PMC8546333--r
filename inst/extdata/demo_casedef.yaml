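# Case definition: cardiotoxicity with biologic agents used in rheumatoid
# arthritis. Event terms are an editable preferred-term surrogate list
# (MedDRA itself is licensed; substitute your own PT set).
drugs:
  abatacept: [abatacept, Orencia]
  adalimumab: [adalimumab, Humira]
  tocilizumab: [tocilizumab, Actemra, RoActemra]
  etanercept: [etanercept, Enbrel]
events:
  - Heart failure
  - Cardiac failure
  - Cardiac failure congestive
  - Cardiac insufficiency
  - Cardiac failure acute
  - Cardiomyopathy
  - Weak heart
allowed_roles: [PS, SS]
indication_terms:
  - Rheumatoid arthritis
match_mode: exact
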
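# Reference-dose registry (editable).
# ptmi: provisional tolerable monthly intake, ug per kg body weight per month
# bmdl: benchmark dose lower confidence limit, ug per kg body weight per day
# rda:  recommended dietary allowance (Poland, adults 31-50), ug per day
# eu_limits: maximum permissible content, ug per g, by food category
ptmi:
  Cd: 25
bmdl:
  - {element: As, endpoint: skin_cancer, value: 0.06}
  - {element: Pb, endpoint: kidney, value: 0.63}
  - {element: Pb, endpoint: cardiovascular, value: 1.50}
rda:
  - {element: Mn, sex: women, value: 1800}
  - {element: Mn, sex: men, value: 2300}
  - {element: Fe, sex: women, value: 18000}
  - {element: Fe, sex: men, value: 10000}
  - {element: Cu, sex: women, value: 900}
  - {element: Cu, sex: men, value: 900}
  - {element: Zn, sex: women, value: 8000}
  - {element: Zn, sex: men, value: 11000}
eu_limits:
  - {element: Cd, category: herbs, value: 0.1}
  - {element: Cd, category: supplements, value: 1}
  - {element: Pb, category: supplements, value: 3}
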
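# Incretin drug classes approved in Japan during the 2010-2015 window,
# plus common non-incretin hypoglycemic drugs for the indication proxy.
dpp4:
  - sitagliptin phosphate hydrate
  - vildagliptin
  - alogliptin benzoate
  - alogliptin benzoate/pioglitazone hydrochloride
  - linagliptin
  - teneligliptin hydrobromide hydrate
  - anagliptin
  - saxagliptin hydrate
glp1:
  - exenatide
  - liraglutide
  - lixisenatide
hypoglycemic:
  - metformin hydrochloride
  - glimepiride
  - glibenclamide
  - gliclazide
  - pioglitazone hydrochloride
  - voglibose
  - miglitol
  - acarbose
  - nateglinide
  - mitiglinide calcium hydrate
  - insulin human
  - insulin glargine
  - insulin aspart
  - insulin lispro
  - insulin detemir
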
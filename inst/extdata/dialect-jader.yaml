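# JADER-style dialect: Japanese column names, 10-year age bands, and
# Japanese sex / drug-role codings.
demo:
  case_id: "識別番号"
  date: "報告年月日"
  age: "年齢"
  sex: "性別"
drug:
  case_id: "識別番号"
  name: "医薬品（一般名）"
  role: "医薬品の関与"
reac:
  case_id: "識別番号"
  pt: "有害事象"
age_format: band
sex_levels: ["男性", "女性"]
role_levels: ["被疑薬", "併用薬", "相互作用"]
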
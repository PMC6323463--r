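{
  "instances": [
    {
      "id": "T001",
      "class": "Test",
      "representative": "platelet",
      "synonyms": ["PFA", "blood disk", "PFT", "platelet aggregation",
                   "platelet function", "thrombocyte", "혈소판"],
      "external_ids": {"umls": "C0005821"}
    },
    {
      "id": "T002",
      "class": "Test",
      "representative": "afp",
      "synonyms": ["alpha-fetoprotein", "total afp", "afp-l3"],
      "external_ids": {"umls": "C0002210"}
    },
    {
      "id": "T003",
      "class": "Test",
      "representative": "hiv test",
      "synonyms": ["human immunodeficiency virus test", "hiv antibody"]
    },
    {
      "id": "T004",
      "class": "Test",
      "representative": "eosinophil",
      "synonyms": ["eosinophil count", "eos"]
    },
    {
      "id": "T005",
      "class": "Test",
      "representative": "uric acid",
      "synonyms": ["urate", "uric acid concentration", "요산"]
    },
    {
      "id": "T006",
      "class": "Test",
      "representative": "bilirubin",
      "synonyms": ["total bilirubin", "tbil"]
    },
    {
      "id": "T007",
      "class": "Test",
      "representative": "amylase",
      "synonyms": ["amy", "아밀라아제"],
      "external_ids": {"umls": "C0002712"}
    },
    {
      "id": "D001",
      "class": "Disease",
      "representative": "acute leukaemia",
      "synonyms": ["leukaemia acute", "leukaemia", "백혈병"]
    },
    {
      "id": "D002",
      "class": "Disease",
      "representative": "anemia",
      "synonyms": ["anaemia", "빈혈"]
    },
    {
      "id": "D003",
      "class": "Disease",
      "representative": "gout",
      "synonyms": ["gouty arthritis"]
    },
    {
      "id": "C001",
      "class": "Category",
      "representative": "inflammation",
      "synonyms": ["inflammatory", "phlogistic", "염증"]
    },
    {
      "id": "S001",
      "class": "Specimen",
      "representative": "serum",
      "synonyms": ["blood serum", "sera", "혈청"]
    }
  ],
  "properties": [
    {"type": "test_disease", "from": "T001", "to": "D001"},
    {"type": "test_disease", "from": "T005", "to": "D003"},
    {"type": "test_specimen", "from": "T002", "to": "S001"},
    {"type": "test_category", "from": "T004", "to": "C001"}
  ]
}
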
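{"title": "Hippocampal neurogenesis after exercise",
 "description": "Immunohistochemistry of dentate gyrus neurons in rats after voluntary wheel running.",
 "metadata": {"organism": "Rattus norvegicus", "assay": "IHC",
   "keywords": ["hippocampus", "neurogenesis", "motor activity"]}}
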
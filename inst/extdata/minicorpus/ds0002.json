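{"title": "Mouse model of diet-induced obesity",
 "description": "Metabolic phenotyping and adipose tissue microarray data from C57BL/6 mice on a high-fat diet.",
 "metadata": {"organism": "Mus musculus", "assay": "microarray",
   "keywords": ["obesity", "adipose tissue", "metabolism"]}}
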
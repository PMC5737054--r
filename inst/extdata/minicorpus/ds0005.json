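{"title": "Cardiac electrophysiology recordings in heart failure",
 "description": "Electrocardiography and myocardium tissue samples from patients with arrhythmias and chronic heart failure.",
 "metadata": {"organism": "Homo sapiens", "assay": "ECG",
   "keywords": ["heart failure", "arrhythmias cardiac", "myocardium"]}}
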
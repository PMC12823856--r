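# Narrow-scope interstitial lung disease preferred-term list.
# One MedDRA-style Preferred Term per line; replace with the licensed
# narrow ILD SMQ term list where a MedDRA licence is available.
Interstitial lung disease
Pneumonitis
Pulmonary fibrosis
Organising pneumonia
Acute interstitial pneumonitis
Idiopathic pulmonary fibrosis
Alveolitis
Allergic alveolitis
Autoimmune lung disease
Pulmonary toxicity
Idiopathic interstitial pneumonia
Progressive massive fibrosis
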
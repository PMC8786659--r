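code	category	condition_label
CHD001	chd	atrial septal defect
CHD002	chd	ventricular septal defect
CHD003	chd	tetralogy of Fallot
AVD001	avd	aortic stenosis
AVD002	avd	aortic insufficiency
AVD003	avd	aortic valve replacement
EXC001	exclusion	acquired rheumatic valve disease
NEU001	neutral	essential hypertension
NEU002	neutral	type 2 diabetes
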
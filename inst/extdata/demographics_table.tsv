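group	sex	age	educ_years	symptoms	ssri_snri	other_medication
FND-movt	F	53	13	Dystonia	Citalopram
FND-movt	F	47	11	Parkinsonism	Sertraline
FND-movt	F	57	11	Right hand tremor
FND-movt	M	21	10	Gait difficulties
FND-movt	F	30	11	Left hand tremor
FND-movt	F	60	18	Bilateral leg weakness
FND-movt	F	64	13	Gait difficulties
FND-movt	M	62	13	Myoclonus
FND-movt	F	52	13	Right hand tremor
FND-movt	F	32	18	Bilateral arm tremors
FND-movt	M	21	9	Myoclonus		Clonazepam
FND-movt	F	30	12	Bilateral leg weakness and speech difficulties
FND-movt	F	42	11	Right leg tremor	Citalopram
FND-movt	M	25	13	Dystonia
FND-movt	F	22	11	Bilateral arm weakness and tremors
FND-movt	F	38	11	Right hand tremor and bilateral leg weakness	Sertraline
FND-movt	F	35	9	Right hand tremor	Venlafaxine
FND-seiz	F	21	10	Major motor		Pregabalin
FND-seiz	F	22	10	Major motor
FND-seiz	F	22	13	Minor motor
FND-seiz	M	42	10	Major motor	Venlafaxine
FND-seiz	F	28	13	Minor motor
FND-seiz	F	47	13	Atonic
FND-seiz	F	26	18	Atonic
FND-seiz	F	21	13	Minor motor		Levetiracetam
FND-seiz	F	20	13	Atonic
FND-seiz	F	21	10	Major motor
FND-seiz	F	26	10	Minor motor	Citalopram	Clonazepam
FND-seiz	F	37	13	Atonic
FND-seiz	F	20	11	Minor motor
FND-seiz	M	48	11	Atonic	Paroxetine
FND-seiz	F	36	12	Minor motor
FND-seiz	F	30	16	Major motor
FND-seiz	F	38	9	Minor motor
FND-seiz	F	29	10	Atonic
FND-seiz	F	48	11	Major motor	Citalopram	Pregabalin
FND-seiz	F	34	11	Minor motor	Fluoxetine
FND-seiz	F	25	12	Atonic	Sertraline
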
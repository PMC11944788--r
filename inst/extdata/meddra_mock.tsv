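pt	hlt	hlgt	soc	primary_flag
Memory impairment	Memory loss (excl dementia)	Mental impairment disorders	Nervous system disorders	yes
Dementia	Dementia (excl Alzheimer's type)	Mental impairment disorders	Nervous system disorders	yes
Dementia Alzheimer's type	Dementias Alzheimer's type	Mental impairment disorders	Nervous system disorders	yes
Dysstasia	Neurological signs and symptoms NEC	Neurological disorders NEC	Nervous system disorders	yes
Dysgraphia	Speech and language abnormalities	Neurological disorders NEC	Nervous system disorders	yes
Cerebral disorder	Brain disorders NEC	Neurological disorders NEC	Nervous system disorders	yes
Post-herpetic neuralgia	Neuralgia NEC	Neurological disorders NEC	Nervous system disorders	yes
Post-herpetic neuralgia	Herpes viral infections	Viral infectious disorders	Infections and infestations	no
Dyslexia	Speech and language abnormalities	Neurological disorders NEC	Nervous system disorders	yes
Tinel's sign	Neurological signs and symptoms NEC	Neurological disorders NEC	Nervous system disorders	yes
Postural dizziness	Neurological signs and symptoms NEC	Neurological disorders NEC	Nervous system disorders	yes
Movement disorder	Movement disorders NEC	Movement disorders (incl parkinsonism)	Nervous system disorders	yes
Fine motor skill dysfunction	Movement disorders NEC	Movement disorders (incl parkinsonism)	Nervous system disorders	yes
Bradykinesia	Parkinsonism and related conditions	Movement disorders (incl parkinsonism)	Nervous system disorders	yes
Essential tremor	Tremor (excl congenital)	Movement disorders (incl parkinsonism)	Nervous system disorders	yes
Clumsiness	Movement disorders NEC	Movement disorders (incl parkinsonism)	Nervous system disorders	yes
Carpal tunnel syndrome	Mononeuropathies	Peripheral neuropathies	Nervous system disorders	yes
Nerve compression	Mononeuropathies	Peripheral neuropathies	Nervous system disorders	yes
Sciatic nerve neuropathy	Mononeuropathies	Peripheral neuropathies	Nervous system disorders	yes
Polyneuropathy	Peripheral neuropathies NEC	Peripheral neuropathies	Nervous system disorders	yes
Axonal neuropathy	Peripheral neuropathies NEC	Peripheral neuropathies	Nervous system disorders	yes
Sciatica	Lumbar spinal cord and nerve root disorders	Spinal cord and nerve root disorders	Nervous system disorders	yes
Lumbar radiculopathy	Lumbar spinal cord and nerve root disorders	Spinal cord and nerve root disorders	Nervous system disorders	yes
Spinal cord compression	Spinal cord disorders NEC	Spinal cord and nerve root disorders	Nervous system disorders	yes
Spinal cord disorder	Spinal cord disorders NEC	Spinal cord and nerve root disorders	Nervous system disorders	yes
Radicular pain	Nerve root disorders NEC	Spinal cord and nerve root disorders	Nervous system disorders	yes
Sinus headache	Headaches NEC	Headaches	Nervous system disorders	yes
Cold-stimulus headache	Headaches NEC	Headaches	Nervous system disorders	yes
Headache	Headaches NEC	Headaches	Nervous system disorders	yes
Intracranial aneurysm	Aneurysms and dissections CNS	Central nervous system vascular disorders	Nervous system disorders	yes
Carotid arteriosclerosis	Cerebrovascular arteriosclerosis	Central nervous system vascular disorders	Nervous system disorders	yes
Amyotrophic lateral sclerosis	Anterior horn cell disorders	Neuromuscular disorders	Nervous system disorders	yes
Neuromuscular blockade	Neuromuscular junction dysfunction	Neuromuscular disorders	Nervous system disorders	yes
Hypersomnia	Hypersomnic disturbances	Sleep disturbances (incl subtypes)	Nervous system disorders	yes
Leukoencephalopathy	Leukoencephalopathies	Encephalopathies	Nervous system disorders	yes
Metabolic encephalopathy	Toxic and metabolic encephalopathies	Encephalopathies	Nervous system disorders	yes
Cerebral atrophy	Structural brain disorders NEC	Structural brain disorders	Nervous system disorders	yes
Vocal cord paralysis	Accessory and vagus nerve disorders	Cranial nerve disorders (excl neoplasms)	Nervous system disorders	yes
Vocal cord paralysis	Upper respiratory tract signs and symptoms	Respiratory disorders NEC	Respiratory, thoracic and mediastinal disorders	no
Nausea	Nausea and vomiting symptoms	Gastrointestinal signs and symptoms	Gastrointestinal disorders	yes
Pneumonia	Lower respiratory tract infections	Infections - pathogen unspecified	Infections and infestations	yes
Rash	Rashes, eruptions and exanthems NEC	Epidermal and dermal conditions	Skin and subcutaneous tissue disorders	yes
Arthralgia	Joint related signs and symptoms	Joint disorders	Musculoskeletal and connective tissue disorders	yes
Fatigue	Asthenic conditions	General system disorders NEC	General disorders and administration site conditions	yes
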
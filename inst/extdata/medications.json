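["sumatriptan", "zolmitriptan", "naratriptan", "rizatriptan",
 "almotriptan", "eletriptan", "frovatriptan", "lasmiditan",
 "rimegepant", "ubrogepant", "pizotifen", "ergotamine",
 "dihydroergotamine", "clonidine_migraine"]
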
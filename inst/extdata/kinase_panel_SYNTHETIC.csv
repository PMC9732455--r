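"kinase_id","raw_score"
"KIN01",-12
"KIN02",-4.14
"KIN03",-6.1
"KIN04",-4.26
"KIN05",-6.2
"KIN06",-10.08
"KIN07",-9.63
"KIN08",-7.88
"KIN09",-4.73
"KIN10",-7.59
"KIN11",-4.3
"KIN12",-6.42
"KIN13",-9.27
"KIN14",-7.87
"KIN15",-10.94
"KIN16",-8.93
"KIN17",-4
"KIN18",-7.37
"KIN19",-6.24
"KIN20",-4.45
"KIN21",-6.46
"KIN22",-7.11
"KIN23",-10.31
"KIN24",-9.57
"KIN25",-4.2
"KIN26",-8.53
"KIN27",-7.45
"KIN28",-11.5
"KIN29",-7.76
"KIN30",-11.05
"KIN31",-4.46
"KIN32",-9.39
"KIN33",-5.77
"KIN34",-8.54
"KIN35",-4.46
"KIN36",-6.43
"KIN37",-9.34
"KIN38",-5.3
"KIN39",-5.58
"KIN40",-5.95
"KIN41",-6.26
"KIN42",-4.53
"KIN43",-10.29
"KIN44",-5.1
"KIN45",-4.82
"KIN46",-4.72
"KIN47",-4.18
"KIN48",-8.52
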
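term	adj_r2
Surface	0.67
Bottom	0.63
Hydro	0.29
Depth	0.33
Surface+Bottom	0.72
Surface+Hydro	0.78
Surface+Depth	0.71
Bottom+Hydro	0.68
Bottom+Depth	0.63
Hydro+Depth	0.54
Surface+Bottom+Hydro	0.79
Surface+Bottom+Depth	0.73
Surface+Hydro+Depth	0.77
Bottom+Hydro+Depth	0.70
All	0.79
Residuals	0.21
Surface|Bottom	0.09
Surface|Hydro	0.48
Surface|Depth	0.38
Bottom|Surface	0.05
Bottom|Hydro	0.39
Bottom|Depth	0.30
Hydro|Surface	0.11
Hydro|Bottom	0.06
Hydro|Depth	0.21
Depth|Surface	0.04
Depth|Bottom	0.00
Depth|Hydro	0.25
Surface|Hydro+Depth	0.23
Surface|Bottom+Depth	0.10
Surface|Bottom+Hydro	0.11
Bottom|Hydro+Depth	0.16
Bottom|Surface+Depth	0.03
Bottom|Surface+Hydro	0.02
Hydro|Surface+Depth	0.06
Hydro|Bottom+Depth	0.07
Hydro|Surface+Bottom	0.08
Depth|Bottom+Hydro	0.01
Depth|Surface+Hydro	-0.01
Depth|Surface+Bottom	0.02
Surface|Bottom+Hydro+Depth	0.09
Bottom|Surface+Hydro+Depth	0.02
Hydro|Surface+Bottom+Depth	0.05
Depth|Surface+Bottom+Hydro	0.00
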
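mode,length,level,pairing,coef
sustained,short,20,torque_cst,0.74
sustained,long,20,torque_cst,0.74
sustained,short,40,torque_cst,0.74
sustained,long,40,torque_cst,0.61
sustained,short,20,fascicle_cst,0.64
sustained,long,20,fascicle_cst,0.57
sustained,short,40,fascicle_cst,0.63
sustained,long,40,fascicle_cst,0.50
sustained,short,20,torque_fascicle,0.71
sustained,long,20,torque_fascicle,0.67
sustained,short,40,torque_fascicle,0.78
sustained,long,40,torque_fascicle,0.72
sinusoidal,short,20,torque_cst,0.78
sinusoidal,long,20,torque_cst,0.77
sinusoidal,short,40,torque_cst,0.77
sinusoidal,long,40,torque_cst,0.66
sinusoidal,short,20,fascicle_cst,0.71
sinusoidal,long,20,fascicle_cst,0.73
sinusoidal,short,40,fascicle_cst,0.74
sinusoidal,long,40,fascicle_cst,0.62
sinusoidal,short,20,torque_fascicle,0.87
sinusoidal,long,20,torque_fascicle,0.89
sinusoidal,short,40,torque_fascicle,0.91
sinusoidal,long,40,torque_fascicle,0.89
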
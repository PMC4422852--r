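peptide,ion_type,frag_index,neutral_loss,abundance
R6pS4,z_radical,12,0,2.06
R6pS4,z_prime,12,0,1.39
R6pS4,z_radical,13,0,0.54
R6pS4,z_radical,12,97.976896,0.82
R6pS4,z_prime,12,97.976896,0.42
R6pS4,c_radical,11,0,2.34
R6pS4,c,11,0,3.63
R6pS4,c_radical,12,0,3.16
R6pS4,c,12,0,7.39
R6pS4,c,13,0,2.83
R6pS4,c,14,0,5.27
R6pS4,charge_reduced,NA,97.976896,3.61
R6pS4,M_plus_H,NA,0,1.61
R6pS4,charge_reduced,NA,0,16.86
R6pS12,z_radical,10,0,4.65
R6pS12,z_prime,10,0,5.82
R6pS12,z_radical,11,0,3.92
R6pS12,z_prime,11,0,4.58
R6pS12,z_radical,12,0,0.64
R6pS12,z_prime,12,0,0.26
R6pS12,c_radical,12,0,3.24
R6pS12,c,12,0,6.51
R6pS12,c,13,0,0.40
R6pS12,c,14,0,4.34
R6pS12,charge_reduced,NA,97.976896,1.68
R6pS12,M_plus_H,NA,0,1.12
R6pS12,charge_reduced,NA,0,13.16
R6unmod,y,10,0,0.37
R6unmod,z_radical,10,0,5.41
R6unmod,z_prime,10,0,4.44
R6unmod,z_radical,11,0,4.36
R6unmod,z_prime,11,0,3.75
R6unmod,z_radical,12,0,1.42
R6unmod,z_prime,12,0,1.16
R6unmod,z_radical,13,0,1.42
R6unmod,z_prime,13,0,0.92
R6unmod,c_radical,6,0,0.15
R6unmod,c,6,0,0.33
R6unmod,c_radical,7,0,0.51
R6unmod,c,7,0,0.75
R6unmod,c_radical,8,0,0.84
R6unmod,c,8,0,1.25
R6unmod,c_radical,10,0,0.43
R6unmod,c,10,0,1.35
R6unmod,c_radical,11,0,1.51
R6unmod,c,11,0,2.25
R6unmod,c_radical,12,0,1.31
R6unmod,c,12,0,6.38
R6unmod,c,13,0,1.97
R6unmod,c,14,0,2.96
R6unmod,M_plus_H,NA,0,1.39
R6unmod,charge_reduced,NA,0,11.47
L6pS4,z_prime,10,0,0.92
L6pS4,z_radical,11,0,1.25
L6pS4,z_prime,11,0,4.17
L6pS4,z_radical,12,0,0.82
L6pS4,z_prime,12,0,0.66
L6pS4,c_radical,11,0,3.21
L6pS4,c,11,0,3.90
L6pS4,c_radical,12,0,2.53
L6pS4,c,12,0,5.34
L6pS4,c,13,0,2.60
L6pS4,c,14,0,5.48
L6pS4,charge_reduced,NA,97.976896,3.09
L6pS4,M_plus_H,NA,0,2.23
L6pS4,charge_reduced,NA,0,15.33
L6pS12,z_radical,7,0,0.59
L6pS12,z_prime,7,0,2.73
L6pS12,z_prime,8,0,0.78
L6pS12,z_prime,9,0,0.18
L6pS12,z_radical,10,0,2.73
L6pS12,z_prime,10,0,3.62
L6pS12,z_radical,11,0,1.24
L6pS12,z_prime,11,0,1.36
L6pS12,z_radical,12,0,1.54
L6pS12,z_prime,12,0,1.15
L6pS12,z_radical,13,0,0.26
L6pS12,z_prime,13,0,0.35
L6pS12,c_radical,11,0,2.63
L6pS12,c,11,0,2.29
L6pS12,c_radical,12,0,4.72
L6pS12,c,12,0,6.87
L6pS12,c,13,0,1.85
L6pS12,c,14,0,5.11
L6pS12,charge_reduced,NA,97.976896,3.97
L6pS12,M_plus_H,NA,0,2.49
L6pS12,charge_reduced,NA,0,11.39
L6unmod,y,9,0,0.70
L6unmod,z_radical,7,0,5.14
L6unmod,z_prime,7,0,5.53
L6unmod,z_prime,8,0,1.83
L6unmod,z_prime,9,0,4.15
L6unmod,z_radical,10,0,5.73
L6unmod,z_prime,10,0,4.30
L6unmod,z_radical,11,0,3.71
L6unmod,z_prime,11,0,2.72
L6unmod,z_radical,12,0,2.30
L6unmod,z_prime,12,0,1.60
L6unmod,z_radical,13,0,0.98
L6unmod,z_prime,13,0,0.65
L6unmod,c_radical,11,0,2.10
L6unmod,c,11,0,6.34
L6unmod,c,12,0,4.69
L6unmod,c,13,0,2.18
L6unmod,c,14,0,5.11
L6unmod,M_plus_H,NA,0,1.04
L6unmod,charge_reduced,NA,0,8.69
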
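subject,hemisphere,condition,amplitude_mA,frequency_Hz,pulse_width_us,electrode_configuration,stimulation_mode
0309-005,left,SoC,3.5,159,60,"E2: -100%",Directional
0309-005,right,SoC,2.5,159,60,"E5: -100%",Directional
0309-006,left,SoC,3.7,159,60,"E2: -100%",Directional
0309-006,right,SoC,2.0,159,60,"E7: -100%",Directional
0309-007,left,SoC,2.1,130,60,"E5: -100%",Directional
0309-007,right,SoC,2.2,130,60,"E3: -100%",Directional
0309-008,left,SoC,2.7,185,60,"E2: -34%, E3, E4: -33%",Ring
0309-008,right,SoC,1.0,185,60,"E2: -34%, E3, E4: -33%",Ring
0309-009,left,SoC,3.9,130,60,"E4: -100%",Directional
0309-009,right,SoC,1.7,130,60,"E3: -100%",Directional
0309-010,left,SoC,4.6,130,60,"E1: -70%, E2, E3, E4: -10%",Ring
0309-010,right,SoC,3.8,130,60,"E1: -100%",Ring
0309-011,left,SoC,5.0,130,60,"E5: -100%",Directional
0309-011,right,SoC,4.0,130,60,"E4: -100%",Directional
0309-012,left,SoC,2.3,130,60,"E5: -34%, E6, E7: -33%",Ring
0309-012,right,SoC,2.1,130,60,"E5: -34%, E6, E7: -33%",Ring
0309-013,left,SoC,3.6,130,60,"E6: -100%",Directional
0309-013,right,SoC,3.7,130,60,"E3: -100%",Directional
0309-014,left,SoC,4.0,130,60,"E2: -34%, E3, E4: -33%",Ring
0309-014,right,SoC,3.1,130,60,"E2: -100%",Directional
0309-005,left,AgP,2.8,130,60,"E1: -100%",Ring
0309-005,right,AgP,2.9,130,60,"E2: -8%, E4: -22%, E5: -18%, E7: -52%",Directional
0309-006,left,AgP,3.5,130,60,"E1: -100%",Ring
0309-006,right,AgP,4.3,130,60,"E5: -8%, E6, E7: -6%, E8: -80%",Ring
0309-007,left,AgP,2.7,130,60,"E5: -60%, E8: -40%",Directional
0309-007,right,AgP,3.5,130,60,"E1: -50%, E2: -12%, E4: -38%",Directional
0309-008,left,AgP,5.0,130,60,"E2: -2%, E4: -8%, E5: -22%, E7: -68%",Directional
0309-008,right,AgP,3.0,130,60,"E1: -100%",Ring
0309-009,left,AgP,2.8,130,60,"E1: -100%",Ring
0309-009,right,AgP,3.1,130,60,"E1: -100%",Ring
0309-010,left,AgP,5.1,130,60,"E1: -40%, E2: -60%",Directional
0309-010,right,AgP,3.7,130,60,"E1: -70%, E2, E3, E4: -10%",Ring
0309-011,left,AgP,4.2,130,60,"E2: -75%, E3: -25%",Directional
0309-011,right,AgP,3.6,130,60,"E1: -20%, E2: -28%, E3, E4: -26%",Ring
0309-012,left,AgP,2.0,130,60,"E1: -30%, E2: -70%",Directional
0309-012,right,AgP,2.0,130,60,"E2: -70%, E5: -30%",Directional
0309-013,left,AgP,4.5,130,60,"E1: -40%, E2, E3, E4: -20%",Ring
0309-013,right,AgP,5.4,130,60,"E1: -100%",Ring
0309-014,left,AgP,2.5,130,60,"E1: -70%, E2, E3, E4: -10%",Ring
0309-014,right,AgP,2.0,130,60,"E1: -20%, E2: -80%",Directional
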
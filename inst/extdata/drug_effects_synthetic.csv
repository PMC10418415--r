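# Synthetic calibration table for the simulator's per-compound drug-effect
# models. These values are NOT measured data: they encode the qualitative
# dose-response pattern expected of each CiPA risk tier (strong repolarization
# prolongation + EAD propensity for high risk, moderate for intermediate,
# amplitude / rate effects with minimal prolongation for low risk, beat
# cessation at the top dose of dofetilide and quinidine, cycle-length
# irregularity for diltiazem). Concentrations in nM; NA = effect absent.
compound,ec50_p80,emax_p80,hill_p80,ec50_amp,emax_amp,ead_onset_dose,ead_probability_at_top,cessation_dose,irregularity_gain
Dofetilide,1.5,1.2,1.5,5,0.5,1,0.9,10,0.05
Bepridil,300,0.5,1.2,250,0.3,210,0.3,NA,0.05
Quinidine,600,1.2,1.3,1500,0.5,300,0.9,2700,0.05
Terfenadine,10,0.7,1.0,30,0.4,8,0.2,NA,0.05
Chloroquine,3000,0.7,1.2,8000,0.4,2500,0.25,NA,0.1
Chlorpromazine,800,0.75,1.2,2000,0.4,1050,0.25,NA,0.05
Cisapride,20,0.75,1.2,60,0.3,25,0.25,NA,0.05
Diltiazem,40,0.05,1.0,30,0.5,NA,0,NA,0.35
Mexiletine,2000,0.05,1.0,2500,0.35,NA,0,NA,0.08
Ranolazine,5000,0.1,1.0,8000,0.25,NA,0,NA,0.05
Verapamil,50,0.03,1.0,30,0.6,NA,0,NA,0.1
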
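strategy,parameter,mean,sd,distribution,units,source
no_biologic,p_revision,0.03894,,fixed,probability/year,compounded from 5-year revision rate
no_biologic,p_ocs,0.3196,,fixed,probability/year,meta-analysis
no_biologic,p_adverse,0,,fixed,probability/year,not applicable
no_biologic,p_nonadherent,0,,fixed,proportion,not applicable
no_biologic,snot22,50.11,,fixed,score 0-110,meta-analysis
no_biologic,drug_cost_yearly,0,,fixed,CAD/year,not applicable
dupilumab,p_revision,0.00923,0.0022,beta,probability/year,meta-analysis
dupilumab,p_ocs,0.1023,0.0160,beta,probability/year,meta-analysis
dupilumab,p_adverse,0.3183,,beta(2;4.28),probability/year,meta-analysis
dupilumab,p_nonadherent,0.086,,beta(2;21.2),proportion,trial adherence data
dupilumab,snot22,30.20,1.295,beta,score 0-110,meta-analysis
dupilumab,drug_cost_yearly,25516,,fixed,CAD/year,product monograph q2w dosing
mepolizumab,p_revision,0.01686,0.0039,beta,probability/year,meta-analysis
mepolizumab,p_ocs,0.2173,0.0328,beta,probability/year,meta-analysis
mepolizumab,p_adverse,0.3183,,beta(2;4.28),probability/year,meta-analysis
mepolizumab,p_nonadherent,0.112,,beta(2;15.8),proportion,trial adherence data
mepolizumab,snot22,37.22,1.848,beta,score 0-110,meta-analysis
mepolizumab,drug_cost_yearly,27383,,fixed,CAD/year,product monograph q4w dosing
omalizumab,p_revision,0.02592,0.0039,beta,probability/year,meta-analysis
omalizumab,p_ocs,0.1950,0.0911,beta,probability/year,meta-analysis
omalizumab,p_adverse,0.3183,,beta(2;4.28),probability/year,meta-analysis
omalizumab,p_nonadherent,0.052,,beta(2;36),proportion,trial adherence data
omalizumab,snot22,34.02,1.895,beta,score 0-110,meta-analysis
omalizumab,drug_cost_yearly,20000,,fixed,CAD/year,provincial drug benefit price 300mg q4w
shared,ess_cost,3987,,fixed,CAD,government-perspective surgical cost 2021
shared,complication_anaphylaxis,1446,,fixed,CAD,costing literature
shared,complication_arthritis,3562,,fixed,CAD,costing literature
shared,complication_conjunctivitis,179,,fixed,CAD,costing literature
shared,complication_egpa,33292,,fixed,CAD,costing literature
shared,complication_hypersensitivity,601,,fixed,CAD,costing literature
shared,complication_injection_reaction,601,,fixed,CAD,costing literature
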
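name,lower,upper,unit,role,description
volume_fraction,20,40,%,heart,percentage of wall volume determining the unloaded left-ventricular cavity volume
sigma_f0,800,1000,Pa,heart,scaling parameter fibre stress
c_f,11.5,12.5,-,heart,curvature parameter fibre stress
sigma_r0,150,250,Pa,heart,scaling parameter radial stress
c_r,8.5,9.5,-,heart,curvature parameter radial stress
sigma_a0,90000,250000,Pa,heart,scaling parameter active stress
c_a,1000000,2000000,-,heart,curvature parameter active stress
l_s0,1.9e-06,2.2e-06,m,heart,sarcomere length at reference state
v_0,9.6e-06,1e-05,m s-1,heart,sarcomere shortening velocity
E,0.4,0.8,MPa,vessel,Young's modulus of the vessel wall
P_vo,0,1067,Pa,systemic,average venous outlet pressure
eta,0.0035,0.0055,Pa s,blood,dynamic viscosity of blood
rho,1040,1060,kg m-3,blood,blood density
mu,0.4,0.6,-,vessel,Poisson ratio of the vessel wall
HF,60,70,b.p.m.,heart,heart frequency
q_tot,200,300,ml min-1,coronary,total resting flow to the coronary arteries
compliance_scale,1.0,2.0,-,systemic,systemic Windkessel compliance scaling factor
resistance_scale,0.71,1.43,-,systemic,systemic Windkessel peripheral resistance scaling factor
R_art_frac,0.18518519,0.33333333,-,coronary_micro,arterial resistance fraction of the branch microvascular total
R_myo1_frac,0.25925926,0.40740741,-,coronary_micro,first myocardial resistance fraction of the branch microvascular total
R_myo2_frac,0.25925926,0.40740741,-,coronary_micro,second myocardial resistance fraction of the branch microvascular total
R_ven_frac,0,0.14814815,-,coronary_micro,venous resistance fraction of the branch microvascular total
C_art,0.02,0.38,mm3 Pa-1,coronary_micro,coronary arterial compliance
C_myo,0.053,1.007,mm3 Pa-1,coronary_micro,coronary myocardial compliance
C_ven,0.065,1.235,mm3 Pa-1,coronary_micro,coronary venous compliance
P_im_frac,0.5,1,-,coronary_micro,intramyocardial pressure fraction of left-ventricular pressure
sev_LCx,30,70,%,lesion,severity percentage (diameter reduction) of the LCx stenosis
sev_LAD,30,70,%,lesion,severity percentage (diameter reduction) of the LAD stenosis
sev_RCA,30,70,%,lesion,severity percentage (diameter reduction) of the RCA stenosis
len_LCx,3.0,17.0,mm,lesion,length of the LCx stenosis
len_LAD,3.0,37.0,mm,lesion,length of the LAD stenosis
len_RCA,3.0,17.0,mm,lesion,length of the RCA stenosis
sten_position,0.1,0.9,-,lesion,shared fractional position of each stenosis within its host segment
P_mean,60,140,mmHg,systemic,mean arterial pressure
f_hyperemia,2,5,-,coronary,hyperaemia factor applied to all microvascular resistances
P_pul_ven,267,1600,Pa,heart,pulmonary venous pressure (preload)
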
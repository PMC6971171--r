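# Conductance-based neuron parameters for the descending-pathway simulator.
#
# Units: conductances mS/cm2, potentials mV, capacitance uF/cm2, time ms,
# currents uA/cm2, Ca concentration uM.
#
# The motoneuron is a two-compartment (soma + dendrite) model in the style of
# Booth, Rinzel & Kiehn (1997), with a persistent sodium current added to the
# dendrite as in Rybak et al. (2006).  The interneuron is a single-compartment
# reduction carrying only the fast spiking currents (Na, K, leak), as used for
# spinal interneurons in Rybak-style network models.  Values below are
# transcribed from those sources where printed; quantities that the sources
# leave to calibration (leak potentials, synaptic peak conductances, drive
# levels) are set at run time by the calibration routines and only carry
# placeholder defaults here.  Every value can be overridden via
# neuron_params(..., overrides = list()).
#
# version: 1

motoneuron:
  n_compartments: 2
  C: 1.0
  # soma conductances
  g_Na: 120.0
  g_K: 100.0
  g_CaN_S: 14.0
  g_KCa_S: 1.5
  # dendrite conductances
  g_NaP: 0.1
  g_CaN_D: 0.3
  g_CaL: 0.15
  g_KCa_D: 0.6
  # shared
  g_L: 0.51
  g_C: 0.1
  p: 0.1
  E_Na: 55.0
  E_K: -80.0
  E_Ca: 80.0
  E_L: -60.0
  E_SynE: -10.0
  tau_synE: 5.0
  # calcium kinetics
  K_d: 0.2
  f_ca: 0.04
  alpha_ca: 0.1
  k_Ca: 2.0
  # gating kinetics: half-activation (mV), slope (mV; negative => activation),
  # and time-constant parameters per channel
  mNa_V12: -35.0
  mNa_k: -7.8
  mNa_tau: 0.1
  hNa_V12: -55.0
  hNa_k: 7.0
  hNa_tau_scale: 30.0
  hNa_tau_V: -50.0
  hNa_tau_k1: 15.0
  hNa_tau_k2: 16.0
  mK_V12: -28.0
  mK_k: -15.0
  mK_tau_scale: 7.0
  mK_tau_V: -40.0
  mK_tau_k1: 40.0
  mK_tau_k2: 50.0
  mCaN_V12: -30.0
  mCaN_k: -5.0
  mCaN_tau: 4.0
  hCaN_V12: -45.0
  hCaN_k: 5.0
  hCaN_tau: 40.0
  mCaL_V12: -40.0
  mCaL_k: -4.0
  mCaL_tau: 40.0
  mNaP_V12: -47.1
  mNaP_k: -3.1
  mNaP_tau: 0.1
  hNaP_V12: -59.0
  hNaP_k: 8.0
  hNaP_tau_max: 1200.0
  hNaP_tau_V: -59.0
  hNaP_tau_k: 16.0

interneuron:
  n_compartments: 1
  C: 1.0
  g_Na: 120.0
  g_K: 100.0
  g_L: 0.51
  E_Na: 55.0
  E_K: -80.0
  E_L: -64.0
  E_SynE: -10.0
  tau_synE: 5.0
  mNa_V12: -35.0
  mNa_k: -7.8
  mNa_tau: 0.1
  hNa_V12: -55.0
  hNa_k: 7.0
  hNa_tau_scale: 30.0
  hNa_tau_V: -50.0
  hNa_tau_k1: 15.0
  hNa_tau_k2: 16.0
  mK_V12: -28.0
  mK_k: -15.0
  mK_tau_scale: 7.0
  mK_tau_V: -40.0
  mK_tau_k1: 40.0
  mK_tau_k2: 50.0
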
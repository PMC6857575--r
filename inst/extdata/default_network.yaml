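# Published ring-network parameter set (fitted to macaque V1 tuning-curve
# shifts) and the adapt-then-test protocol used for the TAE prediction.
label: adapt-20deg-200ms-then-test-0deg
network:
  tau: 8.0        # membrane time constant, ms
  alpha: 3.88     # rate gain, Hz/mV
  j_lgn: 11.04    # feedforward drive strength, mV
  kappa_lgn: 0.47 # feedforward tuning concentration
  j_cortex: 2.84  # recurrent strength, mV/Hz
  r_ie: 1.24      # inhibition/excitation ratio
  kappa_e: 1.12   # excitatory profile concentration
  kappa_i: 0.56   # inhibitory profile concentration
  n_units: 256
protocol:
  - orientation: 20   # adapter, degrees
    contrast: 1.0
    duration: 200     # ms
  - orientation: 0    # test, degrees
    contrast: 1.0
    duration: 500     # ms
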
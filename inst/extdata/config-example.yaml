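# Example eimsim run configuration.  Every entry shown here is the
# package default; omit anything you do not want to override.

e_impact: 70          # eV, impacting electron kinetic energy
n_runs: 1000          # production runs per molecule
workers: 1            # parallel workers (results are worker-independent)
master_seed: 1

md:
  dt: 0.5             # fs, leap-frog time step
  equilibration:
    T: 500            # K, NVT set-point
    duration: 12500   # fs
  sampling:
    duration: 25000   # fs, NVE conformer trajectory
    n_snapshots: 1000
  production:
    max_time: 10000   # fs per cascade level
  thermostat_tau: 100 # fs, Berendsen coupling constant
  check_interval: 20  # steps between fragmentation checks (10 fs)
  persistence: 3      # consecutive identical splits before acceptance
  depth_cap: 6        # maximum cascade recursion depth
  bond_scale: 1.2     # covalent-radius multiplier for bond detection

ionization:
  a: 0.2              # eV/atom, IEE density width knob
  b: 1.0              # dimensionless shape knob
  mode_per_atom: 0.6  # eV/atom, IEE density mode
  ic_alpha: 0.5       # 1/eV, energy-gap-law exponent
  ic_k_h: 2           # ps, zero-gap internal-conversion time
  # fixed_iee: 0      # uncomment to bypass IEE sampling (testing)

electronic_temperature:
  ground: 300         # K, Fermi smearing for neutral-stage backends
  production: 5000    # K, for hot-ion propagation backends

spectrum:
  prune: 1.0e-4       # isotopologue pruning threshold
  write_prune_percent: 0.1  # writers drop sticks below this % of base
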
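# Example run configuration. Only values that differ from the package
# defaults need to be stated; everything else is merged in from
# default_config(). Units: seconds and deg/s throughout.
trajectory:
  amplitude: 60        # signed peak yaw velocity; positive = leftward
  movement_duration: 1.0
  onset: 0.5
world:
  sensor_noise_sd: 10  # healthy canal measurement noise
  bvp_noise_sd: 2      # neuronal noise of the deafferented signal
inference:
  n_particles: 5000
  resample_threshold: 0.5
run:
  n_seeds: 20
  master_seed: 1
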
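# 60-direction electrostatically optimized scheme (antipodal Coulomb
# energy minimized from a Fibonacci start); equal-weight averages over
# this set integrate the smooth even angular profiles met here to a few
# 1e-4, which keeps the discrete spherical mean close to its continuum
# value even for highly concentrated fibre distributions.
dirs60 <- matrix(c(
  0.38580202, 0.16309307, 0.90805146,
  -0.23592086, 0.25297820, 0.93826616,
  0.25535495, -0.13723694, 0.95705793,
  0.07734451, -0.40893860, 0.90927831,
  -0.02431400, 0.52977301, 0.84779089,
  0.58339736, -0.07979050, 0.80825800,
  -0.67013189, -0.03727784, 0.74130534,
  0.30599057, 0.47299580, 0.82622318,
  -0.12447822, -0.63200952, 0.76489812,
  -0.65547593, 0.47522003, 0.58695589,
  0.80269738, 0.04116166, 0.59496440,
  -0.44947769, -0.61824769, 0.64477872,
  0.05857057, 0.91584444, 0.39723853,
  0.36232092, -0.82983723, 0.42437450,
  -0.81593076, 0.18241849, 0.54861689,
  0.78330281, 0.41797622, 0.46014409,
  -0.25293434, -0.83429086, 0.48988058,
  -0.44810481, 0.74661663, 0.49169675,
  0.81255525, -0.48714278, 0.32007169,
  -0.73335915, -0.50603720, 0.45399417,
  0.42554327, 0.81651822, 0.39014218,
  -0.28152446, -0.94242134, 0.18051592,
  -0.54715633, 0.82942710, 0.11256393,
  0.93281185, 0.16136568, 0.32221604,
  -0.77717060, -0.61721399, 0.12268966,
  -0.03704496, 0.99773664, 0.05611833,
  0.81257619, -0.58284769, 0.00291757,
  -0.99749649, -0.06575307, -0.02602471,
  0.70034233, 0.66647666, 0.25559633,
  0.04030418, -0.96041202, 0.27565255,
  -0.33201050, 0.93794678, -0.10012423,
  0.96025377, -0.03486815, -0.27694206,
  -0.89920428, -0.42200194, -0.11552498,
  0.55725713, 0.83025100, 0.01215622,
  0.26697725, -0.92104495, -0.28354779,
  -0.96148500, 0.27307663, -0.03123707,
  0.92526156, 0.31777554, -0.20714669,
  -0.27470411, -0.95060391, -0.14453323,
  -0.61772949, 0.75417334, -0.22278430,
  0.88769761, -0.36611077, -0.27920577,
  -0.92461482, 0.17251365, -0.33959752,
  0.55053680, 0.76534566, -0.33339953,
  0.14013858, -0.77205326, -0.61991527,
  -0.57489010, 0.60356562, -0.55245807,
  0.84138201, 0.19217832, -0.50511761,
  -0.53192976, -0.59754953, -0.59998774,
  -0.06563368, 0.81957001, -0.56920754,
  0.70611932, -0.63693471, -0.30936983,
  -0.73558311, 0.30888018, -0.60291834,
  0.58477943, 0.34510435, -0.73412261,
  -0.20133125, -0.73505491, -0.64742568,
  -0.26735340, 0.63016359, -0.72898286,
  0.53759169, -0.25702179, -0.80307843,
  -0.62288898, -0.29347470, -0.72517717,
  0.27866470, 0.36897379, -0.88668164,
  0.35246777, -0.54312669, -0.76208915,
  -0.44977473, 0.38218321, -0.80724141,
  0.07358699, 0.09415538, -0.99283419,
  -0.07719101, -0.21318793, -0.97395711,
  0.39116943, 0.05646199, -0.91858506
), ncol = 3, byrow = TRUE)
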
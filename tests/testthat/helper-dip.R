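# Expected dips below were computed with an independent brute-force oracle:
# linear-programming minimisation of the sup distance between the empirical
# CDF and piecewise-linear unimodal CDFs on a dense grid (HiGHS solver),
# frozen at development time to ~1e-10 accuracy.
dip_oracle_cases <- list(
  list(x = c(0.0, 1.0), dip = 0.25),
  list(x = c(1.0, 2.0, 3.0), dip = 0.16666666666666666),
  list(x = c(0.0, 0.1, 0.9, 1.0), dip = 0.22222222222221846),
  list(x = c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0), dip = 0.08333333333333334),
  list(x = c(0.0, 0.45, 0.5, 0.55, 1.0), dip = 0.09999999999999998),
  list(x = c(0.0, 0.0, 0.0, 1.0), dip = 0.125),
  list(x = c(-0.136, 0.556, 0.952, 1.462), dip = 0.125),
  list(x = c(-1.945, -1.459, -0.965, -0.762, -0.488, -0.184, -0.094, -0.019),
       dip = 0.07626440460947326),
  list(x = c(-0.564, -0.43, -0.333, -0.169, 0.217, 0.368, 0.669),
       dip = 0.10268688480978816),
  list(x = c(-0.389, -0.161, 0.037, 0.424, 0.567, 0.819),
       dip = 0.11900369003689404),
  list(x = c(-2.145, -1.833, -0.414, 1.492), dip = 0.125),
  list(x = c(-1.046, 0.294, 0.743, 1.173, 1.494), dip = 0.1),
  list(x = c(-1.357, -1.003, -0.443, -0.376, -0.246, -0.141, 0.177, 0.348),
       dip = 0.08128834355828274),
  list(x = c(-1.64, -1.314, -0.845, -0.397, 0.036, 1.415),
       dip = 0.0868518518518478),
  list(x = c(-1.011, 0.876, 5.705, 5.892, 6.224), dip = 0.14380583680762227),
  list(x = c(-1.459, 1.001, 5.914, 6.077, 6.096), dip = 0.13327003933269987),
  list(x = c(-1.818, -0.936, -0.7, 1.077, 5.574, 5.905, 5.979, 6.026),
       dip = 0.15209009740259544),
  list(x = c(-0.53, 1.172, 5.764, 5.912, 6.023), dip = 0.1459167461074024))

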
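# shared fixtures: the shipped two-site coordination set and small helpers

pair_fecco <- function() lj_pair(-21.49, 1.79)
pair_feo1 <- function() lj_pair(-4.37, 2.74)
pair_feo2 <- function() lj_pair(-6.55, 1.90)

# central-difference force oracle for any energy function
numeric_force <- function(ufun, r, h = 1e-5) {
  -(ufun(r + h) - ufun(r - h)) / (2 * h)
}

# a smooth non-LJ background curve used in decomposition tests
smooth_background <- function(r) 0.8 * exp(-(r - 2.3)^2 / 0.5) - 0.1 * r

kB <- 0.0019872041
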
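# survival points computed exactly from the LQ model (no noise)
noiseless_points <- function(alpha, beta, doses = 0:6) {
  structure(
    data.frame(dose_Gy = doses, sf = exp(-alpha * doses - beta * doses^2),
               sem = 0, n_wells = 16, cells_eff = 80),
    class = c("survival_points", "data.frame")
  )
}

# weighted (1/Y) residual sum of squares, used by brute-force oracles
wrss <- function(alpha, beta, pts) {
  mu <- exp(-alpha * pts$dose_Gy - beta * pts$dose_Gy^2)
  sum((pts$sf - mu)^2 / pts$sf)
}
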
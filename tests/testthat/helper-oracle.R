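# independent oracle for the attenuation fit: brute-force grid search over
# the exponent b, with the intercept profiled out in closed form. Kept free
# of fit_martin_b's code path (no lm).
grid_search_b <- function(depth_m, f_total, z0 = min(depth_m),
                          b_range = c(-1, 3), step = 1e-4) {
  keep <- is.finite(f_total) & f_total > 0
  x <- log(depth_m[keep] / z0)
  y <- log(f_total[keep])
  bs <- seq(b_range[1], b_range[2], by = step)
  sse <- vapply(bs, function(b) {
    a <- mean(y + b * x)
    sum((y - (a - b * x))^2)
  }, numeric(1))
  bs[which.min(sse)]
}
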
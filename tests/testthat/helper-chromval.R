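# shared fixtures, built in code

# the six-level working-standard design
std_levels <- c(0.5, 1, 5, 10, 20, 50)

# noise-free response model on the reference line
noiseless_model <- function(seed = 1) {
  response_model(noise_rsd_by_level = c("1" = 0), seed = seed)
}

# fixed 3-point toy calibration used by the inverse-prediction oracle
toy_fit <- function() {
  fit_calibration(c(1, 2, 3), c(2.1, 3.9, 6.1))
}

# pooled long-format data from a calibration table set
pool_tables <- function(tabs) {
  do.call(rbind, lapply(seq_along(tabs), function(k) {
    df <- tabs[[k]]
    data.frame(curve = k,
               concentration = rep(as.numeric(names(df)), each = nrow(df)),
               response = unlist(df, use.names = FALSE))
  }))
}
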
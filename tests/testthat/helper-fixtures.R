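# Shared fixtures, built once per test run.
t1_ref <- icru46_reference_values()
icru_comp <- icru46_compositions()
alt_comp <- alt_compositions()
elements <- element_data()

# Brute-force OLS oracle: minimise the summed squared error directly.
brute_force_line <- function(x, y) {
  obj <- function(p) sum((y - p[1] - p[2] * x)^2)
  stats::optim(c(0, 1), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1e4))$par
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
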
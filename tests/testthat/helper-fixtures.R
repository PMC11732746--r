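# shared fixtures: default geometry and a standard noise-free campaign

default_geom <- msc_geometry()

# run the full partition -> flux chain on a generated campaign and return
# fluxes merged with the truth ledger
recover_fluxes <- function(camp, geom = default_geom, v_fast = NULL) {
  wide <- deployments_from_long(camp$concentrations)
  parts <- partition_deployments(wide, geom)
  if (is.null(v_fast)) v_fast <- camp$v_fast_true
  fx <- compute_fluxes(parts, geom, v_fast = v_fast)
  truth_cols <- c("deployment_id", "substance",
                  grep("_true$|^b_true$|^f0_true$|^z0$", names(camp$truth),
                       value = TRUE))
  merge(fx, camp$truth[truth_cols], by = c("deployment_id", "substance"))
}

noise_free_campaign <- function(n_profiles = 1, ...) {
  generate_campaign(synthetic_truth(noise_cv = 0, ...),
                    n_profiles = n_profiles, seed = 1)
}
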
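# small, fast cohort configurations used across tests
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(n_individuals = 3000, m_variants = 100, seed = 1L)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}

# minimal association-record table for QC / pairing tests
makeRecords <- function(variant_id, beta, se,
                        effect_allele = rep("A", length(variant_id)),
                        other_allele = rep("G", length(variant_id)),
                        eaf = rep(0.3, length(variant_id)),
                        info = rep(1, length(variant_id)),
                        mac = rep(100, length(variant_id)),
                        flag = rep("ok", length(variant_id))) {
  z <- beta / se
  data.frame(variant_id = variant_id, chromosome = 1L,
             base_pair_location = seq_along(variant_id),
             effect_allele = effect_allele, other_allele = other_allele,
             effect_allele_frequency = eaf, beta = beta,
             standard_error = se, z = z,
             p_value = 2 * stats::pnorm(-abs(z)), n = 1000L,
             n_events = 300L, info = info, mac = mac, flag = flag,
             stringsAsFactors = FALSE)
}

# synthetic effect-pair table (already harmonised)
makePairs <- function(beta_S, beta_P, se_S = 0.01, se_P = 0.02,
                      selected = TRUE) {
  n <- length(beta_S)
  data.frame(variant_id = sprintf("v%05d", seq_len(n)),
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta_S = beta_S, se_S = se_S,
             p_S = 2 * stats::pnorm(-abs(beta_S / se_S)),
             beta_P = beta_P, se_P = se_P,
             p_P = 2 * stats::pnorm(-abs(beta_P / se_P)),
             selected = selected, stringsAsFactors = FALSE)
}
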
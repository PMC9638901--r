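# shared fixtures: a standard one-replicate design and quick sampler settings
std_design <- function()
  tilacDesign(c("fwd1", "rev1", "unl1"),
              c("forward", "reverse", "unlabelled"))

# reduced sampler settings for unit tests where full chains are unnecessary
quick_fit <- function(x, ...)
  fitTilac(x, chains = 2L, warmup = 300L, iter = 300L, ...)

# generative per-read labelled/background rates implied by the default
# simulator settings (200 bases, quarter-U/quarter-G composition)
default_rates <- function()
  data.frame(mut_type = c("TC", "GA"),
             lambda_u = c(200 * 0.25 * 0.001, 200 * 0.25 * 0.004),
             lambda_l = c(200 * 0.25 * 0.05, 200 * 0.25 * 0.02))

# hand-rolled tally rows for toy aggregation tests
toy_tally <- function(y_TC, y_GA = 0, gene = "g1", sample = "s1",
                      n_U = 50L, n_G = 50L, feature = "exonic") {
  n <- max(length(y_TC), length(y_GA))
  data.frame(read_id = paste0("r", seq_len(n)), sample_id = sample,
             gene_id = gene, feature_class = feature,
             n_U = n_U, n_G = n_G,
             y_TC = rep_len(y_TC, n), y_GA = rep_len(y_GA, n),
             stringsAsFactors = FALSE)
}
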
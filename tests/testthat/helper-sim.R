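# Shared small fixtures built in code.

# A small two-trait study used across tests: structured panel, focal trait
# of low heritability, well-predicted correlated secondary trait.
small_study <- function(n = 120, p = 800, h2 = c(0.26, 0.9), cor_g = 0.85,
                        cor_r = 0.4, seed = 2024) {
  cfg <- sim_config(n, p, heritabilities = h2,
                    genetic_correlation = cor_g,
                    residual_correlation = cor_r,
                    n_subpops = max(2L, round(n / 10)),
                    seed = seed)
  st <- sim_phenotypes(sim_genotypes(cfg), cfg)
  colnames(st$phenotypes) <- c("yield", "height")
  colnames(st$true_breeding_values) <- c("yield", "height")
  st$A <- vanraden_grm(st$genotypes)
  st
}
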
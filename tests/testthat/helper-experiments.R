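# Study-scale experiment runs are expensive; the reproduction suite shares
# them through this per-session cache.
.exp_cache <- new.env(parent = emptyenv())

cached_experiment <- function(name, fn) {
  if (is.null(.exp_cache[[name]])) .exp_cache[[name]] <- fn()
  .exp_cache[[name]]
}

# Per-rat mean over a phase/block window, plus group labels.
rat_means <- function(trials, phase, blocks = NULL) {
  d <- trials[trials$phase %in% phase, ]
  if (!is.null(blocks)) d <- d[d$block %in% blocks, ]
  P <- tapply(d$P, d$rat, mean)
  grp <- tapply(d$group, d$rat, `[`, 1)
  data.frame(rat = as.integer(names(P)), group = as.character(grp),
             P = as.numeric(P))
}

anova_group_p <- function(fit) {
  tab <- summary(fit)[[1]]
  tab[trimws(rownames(tab)) == "group", "Pr(>F)"]
}
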
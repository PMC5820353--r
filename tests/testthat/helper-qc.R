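# build synthetic per-stack depth profiles directly
sim_profiles <- function(n_stacks, lambda = 6, att_bins = integer(0),
                         att = 0.2, channels = c("vgat", "gad67"),
                         int_mean = 5000, seed = 1) {
  withr::with_seed(seed, {
    g <- tidyr::expand_grid(
      stack_id = sprintf("st%02d", seq_len(n_stacks)),
      channel = channels, bin = 1:40
    )
    fac <- ifelse(g$bin %in% att_bins, att, 1)
    g$n_objects <- rpois(nrow(g), lambda * fac)
    g$mean_intensity <- ifelse(
      g$n_objects > 0,
      rnorm(nrow(g), int_mean * fac, int_mean * 0.08 / sqrt(pmax(g$n_objects, 1))),
      NA_real_
    )
    g
  })
}

# independent brute-force oracle: significant bin pairs via stats::aov +
# stats::TukeyHSD (gated on the omnibus test), then exhaustive scan of every
# contiguous run
oracle_window <- function(profiles, alpha = 0.05) {
  sig <- matrix(FALSE, 40, 40)
  fams <- list(c("vgat", "count"), c("gad67", "count"),
               c("marker", "count"), c("gad65", "count"),
               c("vgat", "intensity"), c("gad67", "intensity"))
  for (fam in fams) {
    d <- profiles[profiles$channel == fam[1], ]
    if (!nrow(d)) next
    d$value <- if (fam[2] == "count") as.numeric(d$n_objects) else d$mean_intensity
    d <- d[!is.na(d$value), ]
    ok <- names(which(table(d$bin) >= 2))
    d <- d[d$bin %in% as.integer(ok), ]
    if (length(unique(d$bin)) < 2) next
    d$bin <- factor(d$bin)
    fit <- stats::aov(value ~ bin, data = d)
    pa <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(pa) || pa >= alpha) next
    tk <- stats::TukeyHSD(fit)$bin
    hit <- rownames(tk)[tk[, "p adj"] < alpha]
    for (h in hit) {
      ij <- as.integer(strsplit(h, "-")[[1]])
      sig[min(ij), max(ij)] <- TRUE
    }
  }
  best <- c(1L, 0L)
  for (a in 1:40) for (b in a:40) {
    if (any(sig[a:b, a:b])) break
    if (b - a > best[2] - best[1]) best <- c(a, b)
  }
  best[1]:best[2]
}
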
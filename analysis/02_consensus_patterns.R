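#!/usr/bin/env Rscript
# Consensus-cluster each cohort on the regulator panel (k = 2..10), write
# the CDF/delta-area table and cluster assignments, and plot the consensus
# CDFs and the k = 2 consensus heatmap.

library(m6apattern)
library(ggplot2)

data_dir <- "results/analysis/data"
out <- "results/analysis/consensus"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (nm in c("discovery", "validation")) {
  expr <- read_expression(file.path(data_dir, paste0(nm, "_expression.tsv")))
  regs <- read_gmt(file.path(data_dir, paste0(nm, "_regulators.gmt")))
  res <- consensus_sweep(expr, regs$sets$regulators, ks = 2:10,
                         n_resamples = 500, seed = 11)
  tab <- cdf_and_delta(res)
  k <- select_k(tab)
  message(nm, ": selected k = ", k, "; delta-area at k=3 is ",
          signif(tab$delta_area[tab$k == 3], 3))
  write.table(tab, file.path(out, paste0(nm, "_cdf_delta.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res[[1]]$assignment,
              file.path(out, paste0(nm, "_clusters_k2.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cdf_df <- do.call(rbind, lapply(res, function(r)
    data.frame(k = factor(r$k), x = r$grid, cdf = r$cdf)))
  p1 <- ggplot(cdf_df, aes(x, cdf, color = k)) + geom_step() +
    labs(x = "consensus index", y = "CDF",
         title = paste(nm, "consensus CDF, k = 2..10")) + theme_bw()
  ggsave(file.path(out, paste0(nm, "_cdf.pdf")), p1, width = 6, height = 4)

  cons <- res[[1]]$consensus
  ord <- order(res[[1]]$assignment$label)
  hm <- data.frame(i = rep(seq_along(ord), each = length(ord)),
                   j = rep(seq_along(ord), length(ord)),
                   v = as.vector(cons[ord, ord]))
  p2 <- ggplot(hm, aes(i, j, fill = v)) + geom_raster() +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = paste(nm, "consensus matrix, k = 2"), fill = "consensus") +
    theme_void()
  ggsave(file.path(out, paste0(nm, "_consensus_k2.pdf")), p2,
         width = 5, height = 4.5)
}
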
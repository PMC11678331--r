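# In-code fixtures shared across test files.

# Minimal valid dataset: per-block AGL8 and FT series built from supplied
# functions of time, 2 terms per block by default.
toy_dataset <- function(times = c(0, 7),
                        agl8 = function(t, b) 1 + 0 * t,
                        ftc1 = function(t, b) 0 * t,
                        sd_agl8 = 1, sd_ft = 0,
                        line = "toy", photoperiod = "SD_8h") {
  blocks <- expand.grid(vernalization = c("V", "N"),
                        daytime = c("morning", "evening"),
                        stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    b <- paste(blocks$vernalization[i], blocks$daytime[i], sep = ".")
    do.call(rbind, lapply(c(ft_genes(), target_gene()), function(g) {
      mean <- if (g == "AGL8") agl8(times, b)
      else if (g == "FTc1") ftc1(times, b)
      else 0 * times
      data.frame(vernalization = blocks$vernalization[i],
                 daytime = blocks$daytime[i],
                 term = paste0("T", seq_along(times)),
                 time_days = times, gene = g, mean = mean,
                 sd = if (g == "AGL8") sd_agl8 else sd_ft,
                 stringsAsFactors = FALSE)
    }))
  }))
  ft_dataset(line, photoperiod, rows, require_nonneg_mean = FALSE)
}

# Wide view of one gene's means, rows ordered (block, time).
gene_means <- function(ds, gene) ds$data$mean[ds$data$gene == gene]
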
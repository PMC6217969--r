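# shared fixtures and the independent brute-force enrichment-score oracle

# ranked list straight from metric values (already sorted non-increasing)
make_ranked <- function(metric, gene_ids = sprintf("g%02d", seq_along(metric))) {
  structure(data.frame(gene_id = gene_ids, metric = metric,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# literal element-by-element running-sum walk: visits every rank, applies the
# increment/decrement rule directly and tracks both extremes. Independent of
# the hit-position shortcut the engine uses.
oracle_es <- function(metric, hit, weight) {
  n <- length(metric)
  s <- sum(hit)
  w <- abs(metric)^weight
  tot <- sum(w[hit])
  run <- 0; up <- 0; dn <- 0; up_at <- 0L; dn_at <- 0L
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (tot > 0) w[i] / tot else 1 / s
    } else -1 / (n - s)
    if (run > up) { up <- run; up_at <- i }
    if (run < dn) { dn <- run; dn_at <- i }
  }
  # positive wins a tie of extremes; the comparison carries a small
  # tolerance because the sequential walk accumulates rounding error at
  # mathematically exact ties
  if (up + dn >= -1e-12) list(es = up, peak = up_at)
  else list(es = dn, peak = dn_at + 1L)
}

# minimal well-formed GCT / CLS text fixtures
tiny_gct_lines <- function(x) {
  c("#1.2", paste(nrow(x), ncol(x), sep = "\t"),
    paste(c("Name", "Description", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i)
      paste(c(rownames(x)[i], "na", format(x[i, ])), collapse = "\t"),
      character(1)))
}

tiny_matrix <- function(ng = 4, ns = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(ng * ns), ng, ns,
         dimnames = list(sprintf("g%02d", seq_len(ng)),
                         sprintf("s%02d", seq_len(ns))))
}

write_tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
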
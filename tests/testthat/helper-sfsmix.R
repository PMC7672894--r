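# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain elementwise loops so they stay independent of the vectorised
# implementation they check.

quick_config <- function(..., restarts = 3) {
  fit_config(restarts = restarts, ...)
}

# --- brute-force oracles -----------------------------------------------------

oracle_component_density <- function(x, m) {
  # per-point, per-component weighted densities via direct formulas
  out <- matrix(0, length(x), m$k + m$has_tail)
  for (i in seq_along(x)) {
    c0 <- 0
    if (m$has_tail) {
      c0 <- 1
      out[i, 1] <- if (x[i] >= m$tail$scale)
        m$pi[[1]] * m$tail$shape * m$tail$scale^m$tail$shape /
          x[i]^(m$tail$shape + 1)
      else 0
    }
    for (j in seq_len(m$k))
      out[i, c0 + j] <- m$pi[[c0 + j]] *
        stats::dbeta(x[i], m$betas[[j]]$a, m$betas[[j]]$b)
  }
  out
}

oracle_nll <- function(x, m) {
  dens <- oracle_component_density(x, m)
  -sum(log(rowSums(dens)))
}

oracle_responsibilities <- function(x, m) {
  dens <- oracle_component_density(x, m)
  sweep(dens, 1, rowSums(dens), "/")
}

oracle_entropy <- function(z) {
  h <- 0
  for (i in seq_len(nrow(z)))
    for (c in seq_len(ncol(z)))
      if (z[i, c] > 0) h <- h - z[i, c] * log(z[i, c])
  h
}

oracle_reduced_entropy <- function(z, tail_col = 1) {
  keep <- apply(z, 1, which.max) != tail_col
  if (!any(keep)) return(0)
  zz <- z[keep, -tail_col, drop = FALSE]
  zz <- zz / rowSums(zz)
  oracle_entropy(zz)
}

# --- fixture builders --------------------------------------------------------

# a well-separated clonal + subclonal + tail generative model
fixture_model <- function(tail_shape = 1.8, tail_scale = 0.05,
                          means = c(0.45, 0.22), vars = c(0.0015, 0.0012),
                          pi = c(0.3, 0.35, 0.35)) {
  mixture_model(
    tail = list(scale = tail_scale, shape = tail_shape),
    betas = mapply(beta_from_moments, means, vars, SIMPLIFY = FALSE),
    pi = pi)
}

fixture_dataset <- function(n = 1000, seed = 42, model = fixture_model()) {
  sample_model(model, n, seed = seed)
}

# minimal VCF 4.2 text fixture; records is a data frame with chrom, pos,
# ref, alt, depth, alt_reads
write_vcf_fixture <- function(path, records, sample = "TUMOUR") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ad <- paste(r$depth - r$alt_reads, r$alt_reads, sep = ",")
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
          "GT:AD:DP", paste("0/1", ad, r$depth, sep = ":"), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
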
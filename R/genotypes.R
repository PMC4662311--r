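#' Multilocus genotype table
#'
#' Long-format container for diploid microsatellite genotypes: one row per
#' sample x locus, alleles stored as integer fragment sizes (bp). A missing
#' genotype has both alleles \code{NA}; half-missing genotypes are invalid.
#' Genotypes are unordered pairs and are stored in canonical order
#' (\code{allele_a <= allele_b}) so that (a,b) and (b,a) compare equal
#' everywhere downstream. The locus set is completed to be identical across
#' samples (absent combinations become missing).
#'
#' @param df data.frame with columns \code{sample_id}, \code{locus_id},
#'   \code{allele_a}, \code{allele_b}.
#' @return A \code{genotype_table} (data.frame subclass), canonicalized and
#'   grid-completed, sorted by sample then locus.
#' @export
genotype_table <- function(df) {
  need <- c("sample_id", "locus_id", "allele_a", "allele_b")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$locus_id <- as.character(df$locus_id)
  for (col in c("allele_a", "allele_b")) {
    a <- df[[col]]
    if (is.logical(a) && all(is.na(a))) a <- as.integer(a)
    if (!is.numeric(a)) stop("non-integer allele in column ", col)
    if (any(!is.na(a) & a != round(a)))
      stop("non-integer allele in column ", col)
    df[[col]] <- as.integer(a)
  }
  half <- xor(is.na(df$allele_a), is.na(df$allele_b))
  if (any(half))
    stop("half-missing genotype (one allele present, one missing) for sample ",
         df$sample_id[which(half)[1]], " locus ", df$locus_id[which(half)[1]])
  if (anyDuplicated(df[c("sample_id", "locus_id")]))
    stop("duplicated sample x locus rows")
  # canonical unordered pair
  swap <- !is.na(df$allele_a) & df$allele_a > df$allele_b
  tmp <- df$allele_a[swap]
  df$allele_a[swap] <- df$allele_b[swap]
  df$allele_b[swap] <- tmp
  # complete the sample x locus grid with MISSING
  samples <- unique(df$sample_id)
  loci <- sort(unique(df$locus_id))
  full <- expand.grid(locus_id = loci, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- merge(full, df, by = c("sample_id", "locus_id"), all.x = TRUE,
                sort = FALSE)
  full <- full[order(match(full$sample_id, samples),
                     match(full$locus_id, loci)),
               c("sample_id", "locus_id", "allele_a", "allele_b")]
  rownames(full) <- NULL
  class(full) <- c("genotype_table", "data.frame")
  full
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(unique(x$sample_id)), "samples x",
      length(unique(x$locus_id)), "loci,",
      sum(is.na(x$allele_a)), "missing genotypes\n")
  print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Test two genotype tables for equality up to row order
#' @param a,b genotype_table objects.
#' @return TRUE/FALSE.
#' @export
genotype_tables_equal <- function(a, b) {
  key <- function(g) g[order(g$sample_id, g$locus_id), ]
  a <- key(a); b <- key(b)
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                   check.attributes = FALSE))
}

#' Per-locus allele relative frequencies
#'
#' Frequencies are computed over non-missing genotypes only; each typed
#' individual contributes two allele copies.
#'
#' @param gt genotype_table.
#' @return Object of class \code{allele_freqs}: a named list with one entry
#'   per locus, each \code{list(freq = named numeric vector summing to 1,
#'   n_typed = integer)}. Loci with no typed individuals are dropped with a
#'   warning.
#' @export
allele_frequencies <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  loci <- unique(gt$locus_id)
  out <- list()
  for (l in loci) {
    rows <- gt[gt$locus_id == l & !is.na(gt$allele_a), ]
    if (nrow(rows) == 0) {
      warning("locus ", l, " has no typed individuals; dropped")
      next
    }
    alleles <- c(rows$allele_a, rows$allele_b)
    tab <- table(alleles)
    freq <- as.numeric(tab) / sum(tab)
    names(freq) <- names(tab)
    out[[l]] <- list(freq = freq, n_typed = nrow(rows))
  }
  class(out) <- "allele_freqs"
  out
}

#' Build an allele_freqs object directly from frequency vectors
#'
#' Convenience constructor used by simulations and tests.
#'
#' @param freq_list named list of named numeric vectors (per-locus allele
#'   frequencies); names of each vector are allele sizes.
#' @param n_typed integer, nominal sample size per locus (default NA).
#' @return allele_freqs object.
#' @export
as_allele_freqs <- function(freq_list, n_typed = NA_integer_) {
  out <- lapply(freq_list, function(f) {
    if (abs(sum(f) - 1) > 1e-9) stop("frequency vector does not sum to 1")
    if (is.null(names(f))) stop("allele frequencies must be named by allele")
    list(freq = f, n_typed = n_typed)
  })
  class(out) <- "allele_freqs"
  out
}
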
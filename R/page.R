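# The pAGE directional statistic: sign-concordance between a drug's
# perturbation signature and the aging expression signature over a hallmark
# module, with permutation significance and cross-level direction classing.

#' Read a per-gene signature
#'
#' Reads either a 2-column TSV (`gene`, `value`) or a GCT (#1.2) matrix;
#' for GCT input, `column` selects the signature (defaults to the first
#' data column). Values are signed per-gene quantities: direction of change
#' with age, or drug perturbation z-scores against the plate reference.
#'
#' @param path TSV or GCT file path.
#' @param column for GCT input, the sample column name.
#' @return named numeric vector (genes -> signed values).
#' @export
readSignature <- function(path, column = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "#1.2")) {
    m <- readGCT(path)
    if (is.null(column)) column <- colnames(m)[1L]
    if (!column %in% colnames(m)) stop("no GCT column named ", column)
    return(m[, column])
  }
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("signature TSV needs gene and value columns")
  v <- as.numeric(df[[2L]])
  if (any(!is.finite(v))) stop("signature values must be finite")
  g <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(g)) stop("signature lists a gene more than once")
  setNames(v, g)
}

#' Read a GCT (#1.2) expression matrix
#'
#' Minimal reader for the CMap-style GCT text format: version line `#1.2`,
#' dimension line, then a table with `Name`, `Description` and one column
#' per signature.
#'
#' @param path GCT file path.
#' @return numeric matrix, genes in rows (rownames), signatures in columns.
#' @export
readGCT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "#1.2")) stop("not a GCT #1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]][1:2])
  tab <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L])
    stop("GCT dimension line disagrees with the table")
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}

#' Write a GCT (#1.2) matrix
#'
#' @param m numeric matrix with gene rownames and signature colnames.
#' @param path output path.
#' @export
writeGCT <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  tab <- data.frame(Name = rownames(m), Description = rownames(m),
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the perturbation instance with the best replicate consistency
#'
#' Among multiple experimental instances of the same drug (cell line, dose,
#' exposure time), keeps the one with the highest `distil_cc_q75`
#' (replicate-consistency metric); ties break lexicographically on
#' `instance_id` for determinism.
#'
#' @param instances data.frame with at least `instance_id` and
#'   `distil_cc_q75` columns.
#' @return the selected row (single-row data.frame).
#' @export
selectInstance <- function(instances) {
  if (is.null(instances) || nrow(instances) == 0L)
    stop("no perturbation instance to select from")
  if (!all(c("instance_id", "distil_cc_q75") %in% names(instances)))
    stop("instances need instance_id and distil_cc_q75 columns")
  if (any(!is.finite(instances$distil_cc_q75)))
    stop("distil_cc_q75 must be finite")
  best <- instances[instances$distil_cc_q75 == max(instances$distil_cc_q75), ]
  best[order(best$instance_id), ][1L, , drop = FALSE]
}

#' The pAGE sign-concordance statistic
#'
#' Over the module genes G carrying a nonzero value in both signatures,
#' each gene contributes `-sign(aging) * sign(drug)`: +1 when the drug
#' shifts the gene against its age-associated direction, -1 when it
#' reinforces it. pAGE is the mean contribution (bounded in [-1, 1]);
#' `weighted = TRUE` weights genes by |drug value| normalised to sum 1.
#' pAGE > 0 marks a beneficial (pro-longevity) direction, pAGE < 0 a
#' deficient (age-accelerating) one.
#'
#' @param aging named numeric aging signature.
#' @param drug named numeric drug perturbation signature.
#' @param moduleGenes hallmark-module gene set.
#' @param weighted use magnitude weighting (default FALSE).
#' @param minAbs exclude genes with |value| below this in either signature
#'   (default 0: only exact zeros are dropped, as they carry no direction).
#' @return a [PAGEResult-class] (z is NA until [pageSignificance()]).
#' @export
pageScore <- function(aging, drug, moduleGenes, weighted = FALSE, minAbs = 0) {
  if (length(aging) == 0L || length(drug) == 0L)
    stop("both signatures must be non-empty")
  G <- intersect(intersect(names(aging), names(drug)), unique(moduleGenes))
  G <- G[abs(aging[G]) > minAbs & abs(drug[G]) > minAbs]
  G <- G[aging[G] != 0 & drug[G] != 0]
  if (length(G) == 0L)
    return(new("PAGEResult", page = NA_real_, z = NA_real_,
               nGenesUsed = 0L, contributions = numeric(0),
               direction = "undefined"))
  contrib <- -sign(aging[G]) * sign(drug[G])
  page <- if (weighted) {
    w <- abs(drug[G]); w <- w / sum(w)
    sum(w * contrib)
  } else mean(contrib)
  new("PAGEResult", page = unname(page), z = NA_real_,
      nGenesUsed = length(G), contributions = contrib,
      direction = if (page > 0) "beneficial"
                  else if (page < 0) "deficient" else "undefined")
}

#' Permutation significance of a pAGE value
#'
#' Null distribution from `nRandom` uniform random gene sets of size |G|
#' drawn from the doubly-measured universe (genes with nonzero values in
#' both signatures); degree plays no role in a transcriptome permutation.
#' Fills the z slot; z is NA when the null is degenerate (e.g. the module
#' covers the whole measured universe).
#'
#' @inheritParams pageScore
#' @param nRandom permutation replicates (default 1000).
#' @param seed master seed.
#' @return a [PAGEResult-class] with z filled.
#' @export
pageSignificance <- function(aging, drug, moduleGenes, nRandom = 1000L,
                             seed = NULL, weighted = FALSE, minAbs = 0) {
  res <- pageScore(aging, drug, moduleGenes, weighted = weighted,
                   minAbs = minAbs)
  if (is.na(res@page)) stop("pAGE undefined: no module gene measured in both signatures")
  universe <- intersect(names(aging), names(drug))
  universe <- universe[abs(aging[universe]) > minAbs &
                       abs(drug[universe]) > minAbs &
                       aging[universe] != 0 & drug[universe] != 0]
  k <- res@nGenesUsed
  seeds <- spawnSeeds(seed, nRandom)
  nullPage <- vapply(seq_len(nRandom), function(i) withSeed(seeds[i], {
    gs <- universe[sample.int(length(universe), k)]
    pageScore(aging, drug, gs, weighted = weighted, minAbs = minAbs)@page
  }), numeric(1))
  sdev <- sd(nullPage)
  if (is.finite(sdev) && sdev > 0)
    res@z <- (res@page - mean(nullPage)) / sdev
  res
}

setMethod("show", "PAGEResult", function(object) {
  cat(sprintf("pAGE = %s over %d genes [%s]",
              ifelse(is.na(object@page), "NA", sprintf("%.3f", object@page)),
              object@nGenesUsed, object@direction))
  if (!is.na(object@z)) cat(sprintf(", z = %.2f", object@z))
  cat("\n")
})

#' Classify a drug's direction across confidence levels
#'
#' A drug is `"pro-longevity"` when pAGE is positive at every confidence
#' level where it is defined, `"age-accelerating"` when negative at every
#' defined level, otherwise `"inconsistent"`.
#'
#' @param pages numeric vector of pAGE values per level (NA = undefined).
#' @return one of `"pro-longevity"`, `"age-accelerating"`,
#'   `"inconsistent"`.
#' @export
classifyDirection <- function(pages) {
  pages <- pages[!is.na(pages)]
  if (length(pages) == 0L) stop("pAGE undefined at every level")
  if (all(pages > 0)) "pro-longevity"
  else if (all(pages < 0)) "age-accelerating"
  else "inconsistent"
}
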
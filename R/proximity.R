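# Closest-distance drug-module proximity, degree-matched significance, and
# the confidence-stratified screening step.

#' Read drug-target mappings
#'
#' TSV with columns `drug_id`, `drug_name`, `target_symbol`, one row per
#' (drug, target) pair.
#'
#' @param path TSV file path.
#' @return named list of drugs; each element is a list with `drug_id`,
#'   `name`, `targets` (character vector).
#' @export
readDrugTargets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("drug_id", "drug_name", "target_symbol")
  if (!all(need %in% names(df)))
    stop("drug file needs columns: ", paste(need, collapse = ", "))
  ids <- unique(df$drug_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$drug_id == id, ]
    list(drug_id = id, name = rows$drug_name[1L],
         targets = sort(unique(trimws(rows$target_symbol))))
  })
  setNames(out, ids)
}

#' Raw network proximity of drug targets to a module
#'
#' The mean, over network-mapped drug targets t, of the shortest-path
#' distance from t to the closest module gene (0 when the target is itself
#' in the module). Targets absent from the network, or unreachable from the
#' module, are excluded from the mean and counted in the attributes
#' `nTargetsUsed` / `nTargetsDropped`.
#'
#' @param net an [Interactome-class].
#' @param moduleGenes module gene set S (non-empty after intersection).
#' @param targets drug target set T.
#' @return numeric proximity with count attributes.
#' @export
proximityRaw <- function(net, moduleGenes, targets) {
  moduleGenes <- intersect(unique(moduleGenes), nodes(net))
  if (length(moduleGenes) == 0L) stop("module has no network-mapped gene")
  targets0 <- unique(targets)
  targets <- intersect(targets0, nodes(net))
  if (length(targets) == 0L) stop("drug has no network-mapped target")
  dm <- .pairDist(net, targets, moduleGenes)
  mins <- apply(dm, 1L, min)
  finite <- is.finite(mins)
  if (!any(finite)) stop("drug has no network-mapped target reachable from the module")
  out <- mean(mins[finite])
  attr(out, "nTargetsUsed") <- sum(finite)
  attr(out, "nTargetsDropped") <- length(targets0) - sum(finite)
  out
}

# Null proximity machinery shared by proximitySignificance and the screen:
# per replicate both the module set S and the target set T are replaced by
# degree-matched samples (resample = "both"), or T alone (resample =
# "targets"). Operates on the cached distance matrix when available.
.proximityNull <- function(net, prepS, prepT, moduleGenes, nRandom, seeds,
                           resample) {
  dmFull <- .distMatrix(net)
  vapply(seq_len(nRandom), function(i) withSeed(seeds[i], {
    S <- if (resample == "both") .drawMatched(prepS) else moduleGenes
    T_ <- .drawMatched(prepT)
    dm <- if (!is.null(dmFull)) dmFull[T_, S, drop = FALSE]
          else igraph::distances(net@graph, v = T_, to = S,
                                 algorithm = "unweighted")
    mins <- apply(dm, 1L, min)
    mean(mins[is.finite(mins)])
  }), numeric(1))
}

#' Proximity significance against a degree-matched null
#'
#' Compares the observed proximity with `nRandom` re-measurements in which
#' both the module set and the target set are replaced by degree-matched
#' random gene sets of the same sizes (set `resample = "targets"` for a
#' single-sided null that keeps the module fixed). Significance classes:
#' `z < -1.96` significant, `-1.96 <= z < -1.645` marginal, otherwise ns.
#'
#' @param net an [Interactome-class].
#' @param moduleGenes module gene set S.
#' @param targets drug target set T.
#' @param bins optional [DegreeBinning-class]; built on demand.
#' @param nRandom null replicates (default 1000).
#' @param seed master seed.
#' @param resample `"both"` (default) or `"targets"`.
#' @param zSig,zMarg significance thresholds (defaults -1.96, -1.645).
#' @param minOccupancy passed to [buildDegreeBins()] when `bins` is NULL.
#' @return a [ProximityResult-class].
#' @export
proximitySignificance <- function(net, moduleGenes, targets, bins = NULL,
                                  nRandom = 1000L, seed = NULL,
                                  resample = c("both", "targets"),
                                  zSig = -1.96, zMarg = -1.645,
                                  minOccupancy = 100L) {
  resample <- match.arg(resample)
  if (is.null(bins)) bins <- buildDegreeBins(net, minOccupancy)
  pRaw <- proximityRaw(net, moduleGenes, targets)
  moduleGenes <- intersect(unique(moduleGenes), nodes(net))
  targets <- intersect(unique(targets), nodes(net))
  prepS <- .matchPrep(bins, moduleGenes)
  prepT <- .matchPrep(bins, targets)
  seeds <- spawnSeeds(seed, nRandom)
  nullP <- .proximityNull(net, prepS, prepT, moduleGenes, nRandom, seeds,
                          resample)
  mu <- mean(nullP); sdev <- sd(nullP)
  degenerate <- !is.finite(sdev) || sdev == 0
  z <- if (degenerate) NA_real_ else (as.numeric(pRaw) - mu) / sdev
  new("ProximityResult",
      pRaw = as.numeric(pRaw), nullMean = mu, nullSd = sdev, z = z,
      nTargetsUsed = attr(pRaw, "nTargetsUsed"),
      nTargetsDropped = attr(pRaw, "nTargetsDropped"),
      significance = classifySignificance(z, zSig, zMarg),
      degenerateNull = degenerate)
}

setMethod("show", "ProximityResult", function(object) {
  cat(sprintf("proximity %.3f | null %.3f +/- %.3f | z = %s [%s]\n",
              object@pRaw, object@nullMean, object@nullSd,
              ifelse(is.na(object@z), "NA", sprintf("%.2f", object@z)),
              object@significance))
  if (object@nTargetsDropped > 0L)
    cat("  targets dropped (unmapped/unreachable):", object@nTargetsDropped, "\n")
})

#' Screen a drug library against confidence-stratified hallmark modules
#'
#' One proximity-significance test per (drug, hallmark, level). Hallmark
#' sets whose level cut is empty yield NA rows (status `"empty_set"`);
#' drugs with no network-mapped target yield `"unmapped"` rows and the
#' screen continues. A (drug, hallmark) pair significant at every level
#' whose set is non-empty is flagged all-level consistent — the strongest
#' evidence tier.
#'
#' @param net an [Interactome-class].
#' @param drugs list from [readDrugTargets()] (or equivalently structured).
#' @param hallmarkSetsByLevel named list `levels -> (hallmark -> genes)`,
#'   e.g. `lapply(setNames(1:5, 1:5), buildHallmarkSets, annotations =
#'   ann, net = net)` reordered; see [buildHallmarkSets()].
#' @param bins optional [DegreeBinning-class].
#' @param nRandom,seed,resample,zSig,zMarg as in [proximitySignificance()].
#' @return data.frame (the screen table) with columns drug_id, hallmark,
#'   level, p_raw, null_mean, null_sd, z, significance, n_targets_used,
#'   n_targets_dropped, status, all_level_consistent.
#' @export
screenDrugs <- function(net, drugs, hallmarkSetsByLevel, bins = NULL,
                        nRandom = 1000L, seed = NULL,
                        resample = c("both", "targets"),
                        zSig = -1.96, zMarg = -1.645) {
  resample <- match.arg(resample)
  if (length(drugs) == 0L) stop("no drugs to screen")
  if (length(hallmarkSetsByLevel) == 0L) stop("no hallmark sets to screen against")
  if (is.null(bins)) bins <- buildDegreeBins(net)
  levels_ <- names(hallmarkSetsByLevel)
  marks <- unique(unlist(lapply(hallmarkSetsByLevel, names)))
  rows <- list()
  seeds <- spawnSeeds(seed, length(drugs) * length(marks) * length(levels_))
  k <- 0L
  for (d in names(drugs)) {
    drug <- drugs[[d]]
    mapped <- length(intersect(drug$targets, nodes(net))) > 0L
    for (h in marks) {
      for (lv in levels_) {
        k <- k + 1L
        S <- hallmarkSetsByLevel[[lv]][[h]]
        row <- data.frame(drug_id = d, hallmark = h, level = as.integer(lv),
                          p_raw = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, z = NA_real_,
                          significance = NA_character_,
                          n_targets_used = NA_integer_,
                          n_targets_dropped = NA_integer_,
                          status = "ok", stringsAsFactors = FALSE)
        if (is.null(S) || length(S) == 0L) {
          row$status <- "empty_set"
        } else if (!mapped) {
          row$status <- "unmapped"
        } else {
          pr <- proximitySignificance(net, S, drug$targets, bins = bins,
                                      nRandom = nRandom, seed = seeds[k],
                                      resample = resample,
                                      zSig = zSig, zMarg = zMarg)
          row$p_raw <- pr@pRaw; row$null_mean <- pr@nullMean
          row$null_sd <- pr@nullSd; row$z <- pr@z
          row$significance <- pr@significance
          row$n_targets_used <- pr@nTargetsUsed
          row$n_targets_dropped <- pr@nTargetsDropped
          if (pr@degenerateNull) row$status <- "degenerate_null"
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  # all-level consistency per (drug, hallmark), over levels with usable sets
  tab$all_level_consistent <- FALSE
  for (d in unique(tab$drug_id)) for (h in marks) {
    sel <- tab$drug_id == d & tab$hallmark == h & tab$status != "empty_set"
    if (any(sel) && all(tab$significance[sel] == "significant", na.rm = FALSE) &&
        !anyNA(tab$significance[sel]))
      tab$all_level_consistent[sel] <- TRUE
  }
  rownames(tab) <- NULL
  tab
}

#' Filter screened drugs by cross-level consistency
#'
#' Selects, per hallmark, the drugs whose proximity is significant at
#' enough confidence levels: rule `"all-available"` requires significance
#' at every level whose gene set is non-empty (a hallmark with no top-tier
#' genes is judged on the levels it has), rule `"at-least-k"` requires
#' significance at `minLevels` or more levels. Results are ranked by the
#' best (most negative) z.
#'
#' @param table screen table from [screenDrugs()].
#' @param minLevels minimum number of significant levels for
#'   `"at-least-k"`.
#' @param rule `"all-available"` or `"at-least-k"`.
#' @return named list (per hallmark) of data.frames with drug_id, n_significant,
#'   n_available, best_z, ordered by best_z.
#' @export
consistencyFilter <- function(table, minLevels = 4L,
                              rule = c("all-available", "at-least-k")) {
  rule <- match.arg(rule)
  out <- list()
  if (nrow(table) == 0L) return(out)
  for (h in unique(table$hallmark)) {
    th <- table[table$hallmark == h & table$status != "empty_set", ]
    if (nrow(th) == 0L) next
    res <- do.call(rbind, lapply(split(th, th$drug_id), function(td) {
      nSig <- sum(td$significance == "significant", na.rm = TRUE)
      data.frame(drug_id = td$drug_id[1L], n_significant = nSig,
                 n_available = nrow(td),
                 best_z = if (all(is.na(td$z))) NA_real_ else min(td$z, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    pass <- if (rule == "all-available")
      res$n_significant == res$n_available & res$n_available > 0L
    else res$n_significant >= minLevels
    res <- res[pass, , drop = FALSE]
    res <- res[order(res$best_z), , drop = FALSE]
    rownames(res) <- NULL
    out[[h]] <- res
  }
  out
}
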
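# End-to-end orchestration: the two-step screen (proximity filter, then
# pAGE directionality), candidate reports, validation capture accounting
# and mechanism traces.

#' Configuration for an end-to-end screening run
#'
#' Collects the input paths, the confidence levels to run, the null-model
#' size, the master seed, and the fixed significance thresholds. Every
#' value can also come from a YAML file via [sharpConfigFromYAML()].
#'
#' @param net,annotations,drugs paths to the interactome edge list, the
#'   gene/hallmark/confidence table, and the drug-target table.
#' @param agingSignature path to the aging signature (TSV or GCT).
#' @param drugSignatures path to the drug perturbation signatures (GCT with
#'   one column per drug_id), or NULL when no expression data exist.
#' @param outDir output directory for the run's tables and manifest.
#' @param levels confidence levels to screen (default 1:5).
#' @param nRandom null replicates (>= 100).
#' @param seed master seed.
#' @param zSig,zMarg significance thresholds (must satisfy zSig < zMarg < 0).
#' @param restrictLCC restrict the interactome to its largest component.
#' @param moduleAsLCC reduce each hallmark-level gene set to its LCC before
#'   measuring proximity and pAGE (default FALSE: the full level set).
#' @param weightedPage magnitude-weighted pAGE variant.
#' @param fdrColumn add a Benjamini-Hochberg column over the screen's
#'   normal-tail p-values (the classification itself stays on raw z).
#' @return a `sharpConfig` list.
#' @export
sharpConfig <- function(net, annotations, drugs, agingSignature = NULL,
                        drugSignatures = NULL, outDir = tempfile("sharp"),
                        levels = 1:5, nRandom = 1000L, seed = 1L,
                        zSig = -1.96, zMarg = -1.645,
                        restrictLCC = FALSE, moduleAsLCC = FALSE,
                        weightedPage = FALSE, fdrColumn = FALSE) {
  if (!(zSig < zMarg && zMarg < 0)) stop("need zSig < zMarg < 0")
  if (nRandom < 100L) stop("nRandom must be at least 100")
  structure(list(net = net, annotations = annotations, drugs = drugs,
                 agingSignature = agingSignature,
                 drugSignatures = drugSignatures, outDir = outDir,
                 levels = as.integer(levels), nRandom = as.integer(nRandom),
                 seed = as.integer(seed), zSig = zSig, zMarg = zMarg,
                 restrictLCC = isTRUE(restrictLCC),
                 moduleAsLCC = isTRUE(moduleAsLCC),
                 weightedPage = isTRUE(weightedPage),
                 fdrColumn = isTRUE(fdrColumn)),
            class = "sharpConfig")
}

#' Build a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the [sharpConfig()] arguments.
#' @param ... overrides applied on top of the file's values.
#' @return a `sharpConfig` list.
#' @export
sharpConfigFromYAML <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(sharpConfig, vals)
}

# Stable hash of the configuration for output provenance (outDir excluded:
# the same analysis written elsewhere is the same analysis).
.configHash <- function(config) {
  config <- config[setdiff(names(config), "outDir")]
  json <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  f <- tempfile()
  writeLines(json, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

.writeStamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the two-step screening pipeline end to end
#'
#' Step 1 screens every drug's network proximity against each hallmark's
#' confidence-stratified gene set and keeps the drugs with significant
#' proximity to at least one (hallmark, level). Step 2 computes the pAGE
#' directionality for each kept drug that has a perturbation signature;
#' drugs without one are retained with pAGE = NA (the "lacks expression
#' data" tier). All outputs are written as CSV with a comment-prefixed
#' provenance header (seed and config hash) plus a JSON run manifest, and
#' are byte-identical across runs with the same config and seed.
#'
#' @param config a [sharpConfig()].
#' @return invisibly, a list with `screen` (screen table), `page` (pAGE
#'   table), `candidates` (per-hallmark candidate report), `net`, `sets`,
#'   and the output paths.
#' @export
runSharp <- function(config) {
  stopifnot(inherits(config, "sharpConfig"))
  drugs <- readDrugTargets(config$drugs)
  if (length(drugs) == 0L) stop("drug file lists no drugs")
  net <- loadInteractome(config$net, restrictLCC = config$restrictLCC)
  ann <- readHallmarkAnnotations(config$annotations)
  setsByLevel <- lapply(setNames(config$levels, config$levels), function(lv)
    suppressWarnings(buildHallmarkSets(ann, net, lv)))
  if (config$moduleAsLCC)
    setsByLevel <- lapply(setsByLevel, function(sets)
      lapply(sets, function(s) largestConnectedComponent(net, s)))
  bins <- buildDegreeBins(net)
  seeds <- spawnSeeds(config$seed, 2L)
  screen <- screenDrugs(net, drugs, setsByLevel, bins = bins,
                        nRandom = config$nRandom, seed = seeds[1L],
                        zSig = config$zSig, zMarg = config$zMarg)
  if (config$fdrColumn) {
    pnorm_ <- stats::pnorm(screen$z)
    screen$fdr <- NA_real_
    ok <- !is.na(pnorm_)
    screen$fdr[ok] <- stats::p.adjust(pnorm_[ok], method = "BH")
  }
  proximal <- unique(screen$drug_id[!is.na(screen$significance) &
                                    screen$significance == "significant"])
  # step 2: pAGE for proximal drugs with a perturbation signature
  aging <- if (!is.null(config$agingSignature))
    readSignature(config$agingSignature) else NULL
  sigs <- if (!is.null(config$drugSignatures) &&
              file.exists(config$drugSignatures))
    readGCT(config$drugSignatures) else NULL
  pageRows <- list()
  pageSeeds <- spawnSeeds(seeds[2L], max(1L, length(proximal)) *
                          length(setsByLevel) * 16L)
  pk <- 0L
  for (d in proximal) {
    hasSig <- !is.null(aging) && !is.null(sigs) && d %in% colnames(sigs)
    drugSig <- if (hasSig) sigs[, d] else NULL
    sigHallmarks <- unique(screen$hallmark[screen$drug_id == d &
      !is.na(screen$significance) & screen$significance == "significant"])
    for (h in sigHallmarks) {
      for (lv in names(setsByLevel)) {
        pk <- pk + 1L
        S <- setsByLevel[[lv]][[h]]
        row <- data.frame(drug_id = d, hallmark = h, level = as.integer(lv),
                          page = NA_real_, z = NA_real_,
                          n_genes_used = NA_integer_,
                          status = if (hasSig) "ok" else "no_signature",
                          stringsAsFactors = FALSE)
        if (hasSig && length(S) > 0L) {
          pg <- tryCatch(
            pageSignificance(aging, drugSig, S, nRandom = config$nRandom,
                             seed = pageSeeds[pk],
                             weighted = config$weightedPage),
            error = function(e) NULL)
          if (!is.null(pg)) {
            row$page <- pg@page; row$z <- pg@z
            row$n_genes_used <- pg@nGenesUsed
          } else row$status <- "page_undefined"
        } else if (hasSig) row$status <- "empty_set"
        pageRows[[length(pageRows) + 1L]] <- row
      }
    }
  }
  pageTab <- if (length(pageRows)) do.call(rbind, pageRows)
    else data.frame(drug_id = character(0), hallmark = character(0),
                    level = integer(0), page = numeric(0), z = numeric(0),
                    n_genes_used = integer(0), status = character(0))
  candidates <- .candidateReport(screen, pageTab)
  # outputs
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(paste0("# seed: ", config$seed),
             paste0("# config_hash: ", .configHash(config)))
  paths <- list(screen = file.path(config$outDir, "screen_table.csv"),
                page = file.path(config$outDir, "page_table.csv"),
                candidates = file.path(config$outDir, "candidates.csv"),
                manifest = file.path(config$outDir, "run_manifest.json"))
  .writeStamped(screen, paths$screen, stamp)
  .writeStamped(pageTab, paths$page, stamp)
  .writeStamped(candidates, paths$candidates, stamp)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = .configHash(config),
         n_drugs = length(drugs), n_proximal = length(proximal),
         levels = config$levels, n_random = config$nRandom),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(screen = screen, page = pageTab, candidates = candidates,
                 net = net, sets = setsByLevel, paths = paths))
}

# Per-hallmark ranked candidates: every drug significant at >= 1 level,
# with its evidence tier, cross-level direction class and best statistics.
.candidateReport <- function(screen, pageTab) {
  rows <- list()
  for (h in unique(screen$hallmark)) {
    sh <- screen[screen$hallmark == h & screen$status != "empty_set", ]
    for (d in unique(sh$drug_id)) {
      sd_ <- sh[sh$drug_id == d, ]
      nSig <- sum(sd_$significance == "significant", na.rm = TRUE)
      if (nSig == 0L) next
      nAvail <- nrow(sd_)
      tier <- if (nSig == nAvail) "all-level"
              else sprintf("%d-of-%d", nSig, nAvail)
      pd <- pageTab[pageTab$drug_id == d & pageTab$hallmark == h, ]
      pages <- if (nrow(pd)) pd$page else NA_real_
      direction <- if (all(is.na(pages))) {
        if (nrow(pd) && any(pd$status == "no_signature")) "no_signature"
        else NA_character_
      } else classifyDirection(pages)
      rows[[length(rows) + 1L]] <- data.frame(
        hallmark = h, drug_id = d, evidence_tier = tier,
        n_significant = nSig, n_levels_available = nAvail,
        best_z = min(sd_$z, na.rm = TRUE),
        best_p_raw = sd_$p_raw[which.min(sd_$z)],
        mean_page = if (all(is.na(pages))) NA_real_
                    else mean(pages, na.rm = TRUE),
        direction = direction, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(hallmark = character(0), drug_id = character(0),
                    evidence_tier = character(0), n_significant = integer(0),
                    n_levels_available = integer(0), best_z = numeric(0),
                    best_p_raw = numeric(0), mean_page = numeric(0),
                    direction = character(0))
  out <- out[order(out$hallmark, out$best_z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Capture accounting for an external validation cohort
#'
#' Counts how many cohort drugs the screen captured: a drug is significant
#' when its best (most negative) proximity z across all hallmarks and
#' levels is below the significant threshold, marginal when the best z
#' falls in the marginal band. The capture fraction counts both tiers.
#' Cohort drugs absent from the screen table stay in the denominator and
#' are flagged unscreened.
#'
#' @param table screen table from [screenDrugs()].
#' @param cohort character vector of drug ids.
#' @param name cohort label.
#' @param zSig,zMarg thresholds (defaults -1.96, -1.645).
#' @return a [ValidationSummary-class].
#' @export
validationCapture <- function(table, cohort, name = "cohort",
                              zSig = -1.96, zMarg = -1.645) {
  cohort <- unique(cohort)
  if (length(cohort) == 0L) stop("cohort must be non-empty")
  unscreened <- setdiff(cohort, table$drug_id)
  nSig <- 0L; nMarg <- 0L
  for (d in setdiff(cohort, unscreened)) {
    zs <- table$z[table$drug_id == d]
    zs <- zs[!is.na(zs)]
    if (length(zs) == 0L) next
    best <- min(zs)
    if (best < zSig) nSig <- nSig + 1L
    else if (best < zMarg) nMarg <- nMarg + 1L
  }
  new("ValidationSummary", cohort = name, nTotal = length(cohort),
      nSignificant = nSig, nMarginal = nMarg,
      captureFraction = (nSig + nMarg) / length(cohort),
      unscreened = unscreened)
}

setMethod("show", "ValidationSummary", function(object) {
  cat(sprintf("%s: %d/%d captured (%.1f%%; %d significant + %d marginal)\n",
              object@cohort, object@nSignificant + object@nMarginal,
              object@nTotal, 100 * object@captureFraction,
              object@nSignificant, object@nMarginal))
  if (length(object@unscreened))
    cat("  unscreened:", paste(object@unscreened, collapse = ", "), "\n")
})

#' Trace how a drug's perturbation reaches a hallmark module
#'
#' Builds the induced subgraph over the drug's targets, their first
#' neighbours, and the module genes within `maxHop` hops of a target, and
#' annotates every node with its module/target membership, its perturbation
#' z from the drug signature (NA when unmeasured) and its shortest-path
#' distance to the module. Non-module target neighbours that touch the
#' module directly — the candidate relay nodes through which the
#' perturbation propagates — are ranked by absolute perturbation.
#'
#' @param net an [Interactome-class].
#' @param moduleGenes hallmark-module gene set.
#' @param drug list with `targets` (as from [readDrugTargets()]).
#' @param drugSig named numeric perturbation signature (optional).
#' @param maxHop hop radius from the targets (default 2).
#' @return list with `nodes` (annotation data.frame), `edges` (2-column
#'   data.frame), `relays` (data.frame ranked by |perturbation|), and
#'   `note` when the module is out of reach.
#' @export
mechanismTrace <- function(net, moduleGenes, drug, drugSig = NULL,
                           maxHop = 2L) {
  targets <- intersect(drug$targets, nodes(net))
  if (length(targets) == 0L) stop("drug has no network-mapped target")
  moduleGenes <- intersect(unique(moduleGenes), nodes(net))
  nbr1 <- unique(unlist(lapply(
    igraph::neighborhood(net@graph, order = 1L, nodes = targets), names)))
  distToTargets <- suppressWarnings(
    igraph::distances(net@graph, v = moduleGenes, to = targets,
                      algorithm = "unweighted"))
  modNear <- moduleGenes[apply(distToTargets, 1L, min) <= maxHop]
  if (length(modNear) == 0L)
    return(list(nodes = NULL, edges = NULL, relays = NULL,
                note = sprintf("no module gene within %d hops of a target",
                               maxHop)))
  keep <- unique(c(targets, nbr1, modNear))
  sub <- igraph::induced_subgraph(net@graph, keep)
  dToMod <- apply(.pairDist(net, keep, moduleGenes), 1L, min)
  nodesTab <- data.frame(
    gene = keep,
    is_target = keep %in% targets,
    in_module = keep %in% moduleGenes,
    dist_to_module = unname(dToMod),
    perturbation_z = if (is.null(drugSig)) NA_real_
                     else unname(drugSig[keep]),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(sub)
  # relays: non-module target neighbours adjacent to a module gene
  relayCand <- setdiff(setdiff(nbr1, targets), moduleGenes)
  isRelay <- vapply(relayCand, function(v) {
    nb <- names(igraph::neighbors(net@graph, v))
    any(nb %in% moduleGenes)
  }, logical(1))
  relays <- nodesTab[nodesTab$gene %in% relayCand[isRelay], , drop = FALSE]
  relays <- relays[order(-abs(ifelse(is.na(relays$perturbation_z), -Inf,
                                     relays$perturbation_z))), , drop = FALSE]
  rownames(relays) <- NULL
  list(nodes = nodesTab,
       edges = data.frame(from = el[, 1L], to = el[, 2L],
                          stringsAsFactors = FALSE),
       relays = relays, note = NULL)
}

#' Extrapolate the expected number of beneficial drugs
#'
#' Applies the profiled cohort's positive rate to the unprofiled
#' candidates: `rate = nPositive / nProfiled`, expected count
#' `round(rate * nUnprofiled)`.
#'
#' @param nUnprofiled candidates without expression profiles.
#' @param nProfiled candidates with profiles (> 0).
#' @param nPositive profiled candidates with a beneficial direction.
#' @return list with `rate` (fraction), `ratePct` (percent, 1 decimal) and
#'   `expected` (integer count).
#' @export
expectedBeneficial <- function(nUnprofiled, nProfiled, nPositive) {
  stopifnot(nProfiled > 0)
  rate <- nPositive / nProfiled
  list(rate = rate, ratePct = round(100 * rate, 1L),
       expected = as.integer(round(rate * nUnprofiled)))
}
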
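# Synthetic-data generator: interactomes with planted hallmark modules,
# drugs at controlled hop distance to a module, and signature pairs at
# controlled sign-concordance. Every stage of the pipeline is testable
# against the ground truth emitted here, without any external download.

#' Specification for a synthetic benchmark instance
#'
#' Defaults describe the standing benchmark conditions: a 2,000-node
#' heavy-tailed background graph (power-law fitness model, exponent 2.5,
#' mean degree 8, emulating an interactome's degree heterogeneity) with one
#' planted 20-gene hallmark module wired at internal density 0.6, drugs of
#' 8 targets planted at controlled hop distance, and signatures measured on
#' 1,000 genes with unit noise scale.
#'
#' @param nNodes number of background nodes.
#' @param degreeModel `"powerlaw"` (static power-law fitness model) or
#'   `"erdos-renyi"`.
#' @param exponent power-law exponent for `"powerlaw"`.
#' @param meanDegree target mean degree (sets the edge count).
#' @param p edge probability for `"erdos-renyi"` (overrides meanDegree
#'   when given).
#' @param modules list of planted modules, each a list with `name`
#'   (hallmark label), `size`, `density` in (0, 1], and optionally
#'   `confidenceMix` (probability weights over confidence levels 1-5).
#' @param drugs list of planted drugs, each a list with `drug_id`,
#'   `module` (hallmark name), `nTargets`, `hop` (0, 1, 2 or
#'   `"random"`), and optionally `rho` (signature concordance in [-1, 1]).
#' @param nGenesMeasured signature universe size.
#' @param noiseSd magnitude scale of signature values.
#' @param seed master seed; all randomness in the generator flows from it.
#' @return a `synthSpec` list.
#' @export
synthSpec <- function(nNodes = 2000L, degreeModel = c("powerlaw", "erdos-renyi"),
                      exponent = 2.5, meanDegree = 8, p = NULL,
                      modules = list(list(name = "Cell senescence",
                                          size = 20L, density = 0.6)),
                      drugs = list(),
                      nGenesMeasured = 1000L, noiseSd = 1, seed = 1L) {
  degreeModel <- match.arg(degreeModel)
  for (m in modules) {
    stopifnot(m$size <= nNodes)
    if (m$density <= 0 || m$density > 1)
      stop("module density must lie in (0, 1]")
  }
  for (d in drugs)
    if (!is.null(d$rho) && abs(d$rho) > 1) stop("rho must lie in [-1, 1]")
  structure(list(nNodes = as.integer(nNodes), degreeModel = degreeModel,
                 exponent = exponent, meanDegree = meanDegree, p = p,
                 modules = modules, drugs = drugs,
                 nGenesMeasured = as.integer(nGenesMeasured),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "synthSpec")
}

#' Generate a synthetic interactome with planted hallmark modules
#'
#' Background edges come from the chosen degree model; each planted
#' module's genes are then wired among themselves at the requested internal
#' density (independent edges), which at density >= 2 log(size)/size makes
#' the module's own LCC cover (almost always) at least 80% of it. Ground
#' truth — module memberships and a gene/hallmark/confidence annotation
#' table — is returned alongside the graph.
#'
#' @param spec a [synthSpec()].
#' @return list with `net` ([Interactome-class]), `modules` (named list of
#'   planted gene vectors), `annotations` (data.frame), `spec`.
#' @export
synthInteractome <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  seeds <- spawnSeeds(spec$seed, 2L + length(spec$modules))
  n <- spec$nNodes
  nodeNames <- sprintf("G%05d", seq_len(n))
  g <- withSeed(seeds[1L], {
    if (spec$degreeModel == "powerlaw") {
      m <- round(n * spec$meanDegree / 2)
      igraph::sample_fitness_pl(n, m, exponent.out = spec$exponent,
                                loops = FALSE, multiple = FALSE)
    } else {
      pr <- spec$p %||% (spec$meanDegree / (n - 1))
      igraph::sample_gnp(n, pr)
    }
  })
  igraph::V(g)$name <- nodeNames
  annRows <- list()
  planted <- list()
  for (i in seq_along(spec$modules)) {
    mod <- spec$modules[[i]]
    genes <- withSeed(seeds[1L + i], {
      gs <- nodeNames[sample.int(n, mod$size)]
      pairs <- utils::combn(gs, 2L)
      keep <- runif(ncol(pairs)) < mod$density
      mix <- mod$confidenceMix %||% rep(1, 5)
      conf <- sample(1:5, length(gs), replace = TRUE, prob = mix)
      list(genes = gs, newEdges = pairs[, keep, drop = FALSE], conf = conf)
    })
    if (ncol(genes$newEdges) > 0L)
      g <- igraph::add_edges(g, as.vector(genes$newEdges))
    planted[[mod$name]] <- sort(genes$genes)
    annRows[[i]] <- data.frame(gene = genes$genes, hallmark = mod$name,
                               confidence = genes$conf,
                               stringsAsFactors = FALSE)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  # an interactome never carries degree-0 proteins, and the edge-list file
  # could not represent them anyway
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  net <- new("Interactome", graph = g,
             report = list(nodes = igraph::vcount(g),
                           edges = igraph::ecount(g),
                           selfLoopsDropped = 0L, duplicatesCollapsed = 0L,
                           synthetic = TRUE),
             cache = new.env(parent = emptyenv()))
  validObject(net)
  planted <- lapply(planted, intersect, y = igraph::V(g)$name)
  ann <- if (length(annRows)) .validateAnnotations(do.call(rbind, annRows))
         else data.frame(gene = character(0), hallmark = character(0),
                         confidence = integer(0))
  ann <- ann[ann$gene %in% igraph::V(g)$name, ]
  list(net = net, modules = planted, annotations = ann, spec = spec)
}

#' Plant a drug at a controlled hop distance from a module
#'
#' Target placement: hop 0 samples targets inside the module (raw proximity
#' 0 by construction); hop 1 from the module's first neighbour shell (raw
#' proximity exactly 1); hop 2 from the second shell (exactly 2);
#' `"random"` samples uniformly outside the module.
#'
#' @param net an [Interactome-class].
#' @param moduleGenes the planted module's gene set.
#' @param nTargets number of targets.
#' @param hop 0, 1, 2 or `"random"`.
#' @param seed RNG seed.
#' @param drugId identifier for the returned record.
#' @return list with `drug_id`, `name`, `targets`.
#' @export
synthDrug <- function(net, moduleGenes, nTargets, hop = 0, seed = NULL,
                      drugId = "synthdrug") {
  allNodes <- nodes(net)
  moduleGenes <- intersect(moduleGenes, allNodes)
  shell <- function(from, exclude) {
    nb <- unique(unlist(lapply(igraph::neighborhood(net@graph, order = 1L,
                                                    nodes = from),
                               function(v) names(v))))
    setdiff(nb, exclude)
  }
  pool <- if (identical(hop, "random")) {
    setdiff(allNodes, moduleGenes)
  } else if (hop == 0) {
    moduleGenes
  } else if (hop == 1) {
    shell(moduleGenes, moduleGenes)
  } else if (hop == 2) {
    s1 <- shell(moduleGenes, moduleGenes)
    shell(s1, union(moduleGenes, s1))
  } else stop("hop must be 0, 1, 2 or \"random\"")
  if (length(pool) < nTargets)
    stop("requested shell holds only ", length(pool), " genes (need ",
         nTargets, ")")
  targets <- withSeed(seed, sort(pool[sample.int(length(pool), nTargets)]))
  list(drug_id = drugId, name = drugId, targets = targets)
}

#' Generate an aging/drug signature pair at controlled concordance
#'
#' Aging signs are uniform +/-1 over the universe. On module genes the drug
#' sign opposes the aging sign with probability (1 + rho)/2, so the
#' expected pAGE over the module equals rho exactly; off-module genes are
#' independent. Magnitudes are |N(0, noiseSd)| times the sign (the
#' statistic only reads signs, so magnitudes exercise scale invariance).
#'
#' @param moduleGenes genes carrying the planted concordance.
#' @param rho concordance in [-1, 1].
#' @param universe measured gene universe (must cover `moduleGenes`).
#' @param noiseSd magnitude scale.
#' @param seed RNG seed.
#' @return list with `aging` and `drug` named numeric signatures.
#' @export
synthSignatures <- function(moduleGenes, rho, universe, noiseSd = 1,
                            seed = NULL) {
  stopifnot(abs(rho) <= 1, all(moduleGenes %in% universe))
  withSeed(seed, {
    nU <- length(universe)
    agingSign <- sample(c(-1, 1), nU, replace = TRUE)
    names(agingSign) <- universe
    drugSign <- sample(c(-1, 1), nU, replace = TRUE)
    names(drugSign) <- universe
    onMod <- universe %in% moduleGenes
    oppose <- runif(sum(onMod)) < (1 + rho) / 2
    drugSign[onMod] <- ifelse(oppose, -agingSign[onMod], agingSign[onMod])
    mag <- function() abs(rnorm(nU, 0, noiseSd)) + 1e-9
    list(aging = agingSign * mag(), drug = drugSign * mag())
  })
}

# Drug signature planted against a fixed aging signature: on module genes
# the sign opposes aging with probability (1 + rho)/2, elsewhere signs are
# independent.
.drugSigAgainst <- function(aging, moduleGenes, rho, noiseSd, seed = NULL) {
  withSeed(seed, {
    universe <- names(aging)
    s <- sample(c(-1, 1), length(universe), replace = TRUE)
    names(s) <- universe
    onMod <- universe %in% moduleGenes
    oppose <- runif(sum(onMod)) < (1 + rho) / 2
    s[onMod] <- ifelse(oppose, -sign(aging[onMod]), sign(aging[onMod]))
    s * (abs(rnorm(length(universe), 0, noiseSd)) + 1e-9)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the interactome, annotations, drugs and signatures described
#' by `spec` and writes them in the formats the public readers consume:
#' `net.tsv` (edge list), `annotations.tsv`, `drugs.tsv`, `aging.tsv`,
#' `drug_sigs.gct` and `truth.json`. Re-loading these files through
#' [loadInteractome()], [readHallmarkAnnotations()], [readDrugTargets()]
#' and [readSignature()] reproduces the in-memory objects exactly.
#'
#' @param spec a [synthSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
writeSynthInputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- synthInteractome(spec)
  net <- world$net
  seeds <- spawnSeeds(spec$seed + 1L, 2L * max(1L, length(spec$drugs)) + 1L)
  drugs <- list()
  for (i in seq_along(spec$drugs)) {
    d <- spec$drugs[[i]]
    mod <- world$modules[[d$module]]
    if (is.null(mod)) stop("drug ", d$drug_id, " names unknown module ", d$module)
    drugs[[d$drug_id]] <- synthDrug(net, mod, d$nTargets, d$hop,
                                    seed = seeds[i], drugId = d$drug_id)
  }
  measured <- withSeed(seeds[length(seeds)], {
    base <- nodes(net)[sample.int(igraph::vcount(net@graph),
                                  min(spec$nGenesMeasured,
                                      igraph::vcount(net@graph)))]
    sort(union(base, unlist(world$modules, use.names = FALSE)))
  })
  # one shared aging signature; each drug signature is planted against it
  aging <- withSeed(seeds[length(seeds) - 1L], {
    s <- sample(c(-1, 1), length(measured), replace = TRUE)
    setNames(s * (abs(rnorm(length(measured), 0, spec$noiseSd)) + 1e-9),
             measured)
  })
  sigCols <- lapply(seq_along(spec$drugs), function(i) {
    d <- spec$drugs[[i]]
    unname(.drugSigAgainst(aging, world$modules[[d$module]],
                           d$rho %||% 0, spec$noiseSd,
                           seed = seeds[max(1L, length(spec$drugs)) + i]))
  })
  drugSigs <- if (length(sigCols)) {
    m <- do.call(cbind, sigCols)
    dimnames(m) <- list(measured, vapply(spec$drugs, `[[`, "", "drug_id"))
    m
  } else NULL
  paths <- list(net = file.path(dir, "net.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                drugs = file.path(dir, "drugs.tsv"),
                aging = file.path(dir, "aging.tsv"),
                drugSigs = file.path(dir, "drug_sigs.gct"),
                truth = file.path(dir, "truth.json"))
  el <- igraph::as_edgelist(net@graph)
  write.table(data.frame(source = el[, 1L], target = el[, 2L]),
              paths$net, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(world$annotations, paths$annotations, sep = "\t",
              quote = FALSE, row.names = FALSE)
  drugTab <- do.call(rbind, lapply(drugs, function(d)
    data.frame(drug_id = d$drug_id, drug_name = d$name,
               target_symbol = d$targets, stringsAsFactors = FALSE)))
  if (is.null(drugTab))
    drugTab <- data.frame(drug_id = character(0), drug_name = character(0),
                          target_symbol = character(0))
  write.table(drugTab, paths$drugs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = names(aging), value = unname(aging)),
              paths$aging, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(drugSigs)) writeGCT(drugSigs, paths$drugSigs)
  truth <- list(modules = world$modules,
                drugs = lapply(drugs, `[[`, "targets"),
                seed = spec$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(net = net, modules = world$modules,
                 annotations = world$annotations, drugs = drugs,
                 aging = aging, drugSigs = drugSigs,
                 paths = paths, spec = spec))
}
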
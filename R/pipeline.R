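#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' blocks: \code{seed}, \code{outDir}, \code{enzymes} (primary, secondary,
#' minLen), \code{genome} (either \code{fasta: path} or synthetic sizing via
#' \code{meanFragmentLen}/optional \code{nFragments}), \code{landscape}
#' (binSize, tadsA, optional tadsB/breakA/breakB for a fused derivative,
#' insulation, alpha, coverage, dispersion, optional loops), \code{viewpoints}
#' (bin indices) and \code{params} (window, mergeGap, binSize, nModels,
#' nKeep, dMin, dMax, zCut, tadSizes, strength).  Unknown top-level keys are
#' rejected before any computation.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list with defaults filled in.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .configError("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .configError("config must be a list or a YAML path")
  known <- c("seed", "outDir", "enzymes", "genome", "landscape",
             "viewpoints", "params")
  bad <- setdiff(names(config), known)
  if (length(bad)) .configError("unknown config key(s): ",
                                paste(bad, collapse = ", "))
  for (key in c("outDir", "landscape", "viewpoints"))
    if (is.null(config[[key]])) .configError("missing config key: ", key)
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  enz <- config$enzymes
  config$enzymes <- list(
    primary = enz$primary %||% "GATC",
    secondary = enz$secondary %||% "GTAC",
    minLen = as.integer(enz$minLen %||% 40L))
  g <- config$genome
  config$genome <- list(fasta = g$fasta,
                        nFragments = g$nFragments,
                        meanFragmentLen = g$meanFragmentLen %||% 400)
  p <- config$params
  config$params <- list(
    window = as.integer(p$window %||% 30L),
    mergeGap = p$mergeGap %||% 500,
    binSize = p$binSize %||% config$landscape$binSize,
    nModels = as.integer(p$nModels %||% 2000L),
    nKeep = as.integer(p$nKeep %||% 20L),
    dMin = p$dMin %||% 1, dMax = p$dMax %||% 100,
    zCut = p$zCut %||% 0,
    tadSizes = p$tadSizes,
    strength = p$strength %||% 1.0)
  ls <- config$landscape
  if (is.null(ls$binSize) || is.null(ls$tadsA))
    .configError("landscape block needs binSize and tadsA")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configError <- function(...) {
  stop(structure(class = c("tadfusion_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.dependencyError <- function(stage, path) {
  stop(structure(class = c("tadfusion_dependency_error", "error", "condition"),
                 list(message = sprintf(
                   "missing artifact %s; run stage '%s' first", path, stage),
                   call = sys.call(-1))))
}

.need <- function(path, stage) {
  if (!file.exists(path)) .dependencyError(stage, path)
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind a single config: \code{digest} (synthetic
#' genome generation and in-silico digestion), \code{simulate} (ground-truth
#' landscape and 4C read simulation), \code{profile} (fragment-end profiles:
#' raw, smoothed, RPM, Z), \code{peaks} (two-sided PAVA background + Tukey
#' fence), \code{model} (restraint-based 3D ensemble), \code{vhic} (virtual
#' Hi-C from the kept mirror cluster), \code{boundaries} (iterative DI
#' consensus), or \code{all} in dependency order.  Every stage writes its
#' declared artifacts plus a JSON manifest (parameters, seed, md5 checksums),
#' and a re-run with an identical config reproduces identical outputs.
#'
#' @param config path to YAML or config list (see
#'   \code{\link{readRunConfig}}).
#' @param stage one of digest, simulate, profile, peaks, model, vhic,
#'   boundaries, all.
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config, stage = c("all", "digest", "simulate",
                                          "profile", "peaks", "model",
                                          "vhic", "boundaries")) {
  stage <- match.arg(stage)
  cfg <- readRunConfig(config)
  out <- cfg$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("digest", "simulate", "profile", "peaks", "model", "vhic", "boundaries")
  else stage
  art <- list()
  for (s in stages) art <- utils::modifyList(art, .runStage(s, cfg))
  invisible(art)
}

.fusedSpec <- function(cfg) {
  ls <- cfg$landscape
  num <- function(x, k) vapply(x, function(e) as.numeric(unlist(e))[k],
                               numeric(1))
  mk <- function(tads, loops = NULL) landscapeSpec(
    nBins = max(num(tads, 2)),
    binSize = ls$binSize, tads = lapply(tads, function(t)
      as.numeric(unlist(t))),
    insulation = ls$insulation %||% 2,
    loops = if (!is.null(loops))
      data.frame(i = num(loops, 1), j = num(loops, 2),
                 strength = num(loops, 3)),
    alpha = ls$alpha %||% 2, coverage = ls$coverage %||% 1e5,
    dispersion = ls$dispersion %||% 0.1, seed = cfg$seed)
  specA <- mk(ls$tadsA, ls$loops)
  if (is.null(ls$tadsB)) return(list(spec = specA,
                                     truth = makeStructure(specA),
                                     fusedTad = NULL, junction = NULL))
  makeFusedLandscape(specA, mk(ls$tadsB), ls$breakA, ls$breakB)
}

.chromName <- function(cfg) if (is.null(cfg$landscape$tadsB)) "chrS" else "der"

.loadMap <- function(cfg, stage = "digest") {
  fa <- .need(file.path(cfg$outDir, "genome.fa"), stage)
  validFragments(digestGenome(fa, cfg$enzymes$primary, cfg$enzymes$secondary,
                              cfg$enzymes$minLen))
}

.loadProfiles <- function(cfg) {
  lapply(cfg$viewpoints, function(v)
    readProfileTSV(.need(file.path(cfg$outDir,
                                   sprintf("profile_vp%d.tsv", v)),
                         "profile")))
}

.runStage <- function(s, cfg) {
  out <- cfg$outDir
  land <- .fusedSpec(cfg)
  chrom <- .chromName(cfg)
  regionLen <- land$spec@nBins * land$spec@binSize
  art <- list()
  if (s == "digest") {
    faPath <- file.path(out, "genome.fa")
    if (!is.null(cfg$genome$fasta)) {
      file.copy(cfg$genome$fasta, faPath, overwrite = TRUE)
    } else {
      nf <- cfg$genome$nFragments %||%
        as.integer(ceiling(1.05 * regionLen / cfg$genome$meanFragmentLen))
      gen <- makeGenome(nf, cfg$genome$meanFragmentLen, seed = cfg$seed,
                        primarySite = cfg$enzymes$primary,
                        secondarySite = cfg$enzymes$secondary,
                        name = chrom, minLen = cfg$enzymes$minLen)
      Biostrings::writeXStringSet(gen, faPath)
    }
    map <- digestGenome(faPath, cfg$enzymes$primary, cfg$enzymes$secondary,
                        cfg$enzymes$minLen)
    suppressMessages(writeFragmentMapBED(map, file.path(out, "fragment_map.bed")))
    art <- list(genome = faPath,
                fragmentMap = file.path(out, "fragment_map.bed"))
  } else if (s == "simulate") {
    map <- .loadMap(cfg)
    writeGroundTruth(land$truth, file.path(out, "truth"))
    counts <- simulate4C(land$truth, unlist(cfg$viewpoints), seed = cfg$seed)
    for (k in seq_along(cfg$viewpoints)) {
      v <- cfg$viewpoints[[k]]
      reads <- binCountsToReads(counts[[k]], map, chrom,
                                land$spec@binSize)
      p <- file.path(out, sprintf("reads_vp%d.tsv", v))
      utils::write.table(reads, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      art[[sprintf("reads_vp%d", v)]] <- p
    }
  } else if (s == "profile") {
    map <- .loadMap(cfg)
    ends <- fragmentEnds(map, chrom = chrom)
    for (v in unlist(cfg$viewpoints)) {
      rp <- .need(file.path(out, sprintf("reads_vp%d.tsv", v)), "simulate")
      reads <- readReadsTSV(rp)
      pos <- (v + 0.5) * land$spec@binSize
      vpFrag <- ends[which.min(abs((ends$fragStart + ends$fragEnd) / 2 - pos)), ]
      vp <- viewpoint(sprintf("vp%d", v), chrom, vpFrag$fragStart)
      prof <- zscoreProfile(normaliseRPM(smoothProfile(
        assignReads(reads, map, vp), cfg$params$window)))
      pp <- file.path(out, sprintf("profile_vp%d.tsv", v))
      writeProfileTSV(prof, pp)
      art[[sprintf("profile_vp%d", v)]] <- pp
      for (layer in c("smoothed", "z"))
        writeProfileBedGraph(prof, layer,
                             file.path(out, sprintf("profile_vp%d_%s.bedGraph",
                                                    v, layer)))
    }
  } else if (s == "peaks") {
    for (prof in .loadProfiles(cfg)) {
      fit <- fit4CBackground(prof, "smoothed")
      ps <- callPeaks(prof, fit, mergeGap = cfg$params$mergeGap)
      v <- sub("vp", "", prof@viewpoint@name)
      p <- file.path(out, sprintf("peaks_vp%s.bed", v))
      writePeaksBED(ps, p)
      art[[sprintf("peaks_vp%s", v)]] <- p
    }
  } else if (s == "model") {
    profs <- .loadProfiles(cfg)
    rs <- buildRestraints(profs, 0, regionLen, cfg$params$binSize,
                          dMin = cfg$params$dMin, dMax = cfg$params$dMax,
                          zCut = cfg$params$zCut)
    er <- runEnsemble(rs, cfg$params$nModels, cfg$params$nKeep,
                      baseSeed = cfg$seed)
    er <- clusterMirror(er)
    writeEnsembleTSV(er, file.path(out, "models"))
    saveRDS(er, file.path(out, "models", "ensemble.rds"))
    art$models <- file.path(out, "models")
  } else if (s == "vhic") {
    erp <- .need(file.path(out, "models", "ensemble.rds"), "model")
    er <- readRDS(erp)
    vh <- virtualHiC(er, "contact")
    p <- file.path(out, "vhic_contact.tsv")
    writeContactMatrixTSV(vh, p)
    art$vhic <- p
  } else if (s == "boundaries") {
    mp <- .need(file.path(out, "vhic_contact.tsv"), "vhic")
    m <- readContactMatrixTSV(mp)
    sizes <- cfg$params$tadSizes %||% defaultTadSizes(m@binSize)
    bc <- consensusBoundaries(m, sizes, strength = cfg$params$strength)
    p <- file.path(out, "boundaries.bed")
    writeBoundariesBED(bc, m, p)
    art$boundaries <- p
  }
  .writeManifest(s, cfg, art)
  art
}

.writeManifest <- function(stage, cfg, art) {
  files <- unlist(art[vapply(art, function(p)
    is.character(p) && file.exists(p) && !dir.exists(p), logical(1))])
  manifest <- list(stage = stage, seed = cfg$seed,
                   params = cfg$params, enzymes = cfg$enzymes,
                   outputs = as.list(if (length(files))
                     tools::md5sum(files) else character(0)))
  jsonlite::write_json(manifest,
                       file.path(cfg$outDir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
}

#' Write / read a full FourCProfile as TSV
#'
#' All coordinate columns and filled signal layers, plus a header comment
#' carrying the viewpoint, so profiles round-trip between pipeline stages.
#'
#' @param profile a FourCProfile.
#' @param path file path.
#' @export
writeProfileTSV <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vp <- profile@viewpoint
  writeLines(sprintf("# viewpoint=%s chrom=%s position=%g radius=%d window=%d discarded=%d rescaled=%d",
                     vp@name, profile@chrom, vp@position, vp@exclusionRadius,
                     profile@window, profile@discarded,
                     as.integer(profile@rescaled)), con)
  df <- data.frame(end = profile@ends, fragIndex = profile@fragIndex,
                   fragStart = profile@fragStart, fragEnd = profile@fragEnd,
                   masked = as.integer(profile@masked))
  for (layer in c("raw", "smoothed", "rpm", "z"))
    if (length(slot(profile, layer))) df[[layer]] <- slot(profile, layer)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTSV
#' @return \code{readProfileTSV}: the reconstructed FourCProfile.
#' @export
readProfileTSV <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[A-Za-z]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  vp <- viewpoint(meta[["viewpoint"]], meta[["chrom"]],
                  as.numeric(meta[["position"]]),
                  as.integer(meta[["radius"]]))
  prof <- new("FourCProfile", viewpoint = vp, chrom = meta[["chrom"]],
              ends = df$end, fragIndex = as.integer(df$fragIndex),
              fragStart = df$fragStart, fragEnd = df$fragEnd,
              masked = df$masked == 1,
              raw = df$raw %||% numeric(0),
              smoothed = df$smoothed %||% numeric(0),
              rpm = df$rpm %||% numeric(0), z = df$z %||% numeric(0),
              window = as.integer(meta[["window"]]),
              discarded = as.integer(meta[["discarded"]]),
              rescaled = meta[["rescaled"]] == "1")
  validObject(prof)
  prof
}
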
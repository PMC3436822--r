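#' @include curation.R rotamer.R steric.R hbond.R stats_report.R synthetic.R
NULL

#' Accept a pre-validated pair without re-running the curation gates
#'
#' Builds an \linkS4class{ApoHoloPair} directly from two structures whose
#' residue numbering already corresponds one-to-one (as the synthetic
#' generator guarantees), defining the site from ligand contacts.  Used for
#' large screened ensembles where the curation verdict is known by
#' construction and re-deriving it per pair would dominate the runtime.
#'
#' @param apo,holo \linkS4class{StructureModel}s with identical residue keys.
#' @param ligand a \linkS4class{LigandInstance} from the Holo form.
#' @param pairID label.
#' @param site optional site keys; default: every protein residue.
#' @return an accepted \linkS4class{ApoHoloPair}.
#' @export
asAcceptedPair <- function(apo, holo, ligand,
                           pairID = paste(pdbID(apo), pdbID(holo), sep = "-"),
                           site = NULL) {
  rtH <- residueTable(holo)
  corr <- data.frame(holoKey = rtH$key, apoKey = rtH$key,
                     resname = rtH$resname)
  if (is.null(site)) site <- rtH$key
  new("ApoHoloPair", pairID = pairID, apo = apo, holo = holo,
      ligand = ligand, correspondence = corr, site = site,
      verdict = "accepted", reasons = character(0), metrics = list())
}

#' Full per-pair side-chain flexibility analysis
#'
#' Runs the analysis stages on an accepted pair: chi angles and rotamer
#' assignment in both forms, the NR quality filter, flexibility calls (with
#' the delta-chi 60-degree comparison method alongside), and optionally the
#' wall steric analysis of the Apo-bound form and the hydrogen-bond network
#' deltas.  Residues without chi angles (Gly/Ala), prolines, disulfide
#' cysteines and residues with incomplete side chains are excluded from the
#' rotamer statistics.
#'
#' @param pair an accepted \linkS4class{ApoHoloPair}.
#' @param wall run the steric analysis.
#' @param hbonds run the hydrogen-bond analysis.
#' @param wallParams a \code{\link{wallParameters}} list.
#' @param includeThr Thr in the hydrogen-bond active list.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{residues} (per-residue data.frame: residueKey,
#'   type, apoRotamer, holoRotamer, apoNR, holoNR, call, deltaChi60,
#'   maxDeltaChi, deltaWall, critical, minimalRotation, bfactor),
#'   \code{siteDelta}, \code{siteCritical}, \code{hbondDeltas}.
#' @export
analyzePair <- function(pair, wall = TRUE, hbonds = TRUE,
                        wallParams = wallParameters(), includeThr = TRUE,
                        tables = chemistryTables()) {
  if (verdict(pair) != "accepted") stop("pair must be accepted")
  corr <- pair@correspondence
  site <- pair@site
  ss <- disulfideCysteines(pair@holo)
  rtH <- residueTable(pair@holo, tables)
  rtA <- residueTable(pair@apo, tables)
  lib <- tables@rotamerLibrary

  rows <- list()
  for (hk in site) {
    ak <- corr$apoKey[match(hk, corr$holoKey)]
    type <- corr$resname[match(hk, corr$holoKey)]
    if (is.na(ak) || type %in% c("GLY", "ALA", "PRO")) next
    if (type == "CYS" && (hk %in% ss || ak %in% disulfideCysteines(pair@apo)))
      next
    if (nChi(type) == 0) next
    resH <- residueAtoms(pair@holo, hk)
    resA <- residueAtoms(pair@apo, ak)
    chH <- computeChis(resH, tables)
    chA <- computeChis(resA, tables)
    if (!chH$complete || !chA$complete) next
    asH <- assignRotamer(chH, lib, tables)
    asA <- assignRotamer(chA, lib, tables)
    qH <- qualityFilter(asH, rtH[match(hk, rtH$key), ])
    qA <- qualityFilter(asA, rtA[match(ak, rtA$key), ])
    call <- classifyFlexibility(asA, asH, qA, qH)
    symIdx <- tables@chiSymmetric[[type]]
    if (is.null(symIdx)) symIdx <- integer(0)
    dchi <- maxAbsDeltaChiVec(chA$chis, chH$chis, symIdx)
    scA <- resA[!resA$name %in% c("N", "CA", "C", "O", "OXT") &
                resA$element != "H", , drop = FALSE]
    rows[[hk]] <- data.frame(
      residueKey = hk, apoKey = ak, type = type,
      apoRotamer = if (asA$nr) "NR" else asA$rotamer,
      holoRotamer = if (asH$nr) "NR" else asH$rotamer,
      apoNR = asA$nr, holoNR = asH$nr, call = call,
      deltaChi60 = deltaChiFlexible(chA, chH, 60, tables),
      maxDeltaChi = max(dchi),
      bfactor = if (nrow(scA)) mean(scA$bfactor) else NA_real_)
  }
  residues <- if (length(rows)) do.call(rbind, rows)
              else data.frame()
  rownames(residues) <- NULL

  siteDelta <- NA_real_; siteCritical <- NA
  if (wall && nrow(residues)) {
    dw <- deltaWall(pair, wallParams, tables)
    calls <- stats::setNames(residues$call, residues$residueKey)
    mdc <- stats::setNames(residues$maxDeltaChi, residues$residueKey)
    cc <- classifyCriticality(dw, calls, wallParams, mdc)
    siteDelta <- dw$siteDelta
    siteCritical <- cc$siteCritical
    m <- match(residues$residueKey, cc$records$residueKey)
    residues$deltaWall <- cc$records$deltaWall[m]
    residues$critical <- cc$records$critical[m]
    residues$minimalRotation <- cc$records$minimalRotation[m]
  } else if (nrow(residues)) {
    residues$deltaWall <- NA_real_
    residues$critical <- NA
    residues$minimalRotation <- NA
  }

  hbondDeltas <- NULL
  if (hbonds && nrow(residues)) {
    holoH <- placePolarHydrogens(pair@holo, tables)
    apoH <- placePolarHydrogens(pair@apo, tables)
    bh <- detectHBonds(holoH, pair@ligand, site, includeThr, tables)
    apoSite <- corr$apoKey[match(site, corr$holoKey)]
    ba <- detectHBonds(apoH, NULL, apoSite, includeThr, tables)
    ch <- hbondCounts(bh, site)
    ca <- hbondCounts(ba, apoSite)
    ca$residueKey <- site  # report on Holo keys
    hbondDeltas <- hbondDelta(ca, ch)
  }

  list(residues = residues, siteDelta = siteDelta,
       siteCritical = siteCritical, hbondDeltas = hbondDeltas)
}

#' Analyze a synthetic ensemble
#'
#' Applies \code{\link{analyzePair}} to each generated pair (wall and
#' hydrogen-bond stages optional) and aggregates per-residue records and
#' per-site flexible counts for the reporting functions.
#'
#' @param ensemble list from \code{\link{generateEnsemble}} (or of
#'   \code{\link{generatePair}} results).
#' @param wall,hbonds stage switches, off by default for speed at ensemble
#'   scale.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{records} (row-bound residue tables with pairID),
#'   \code{siteCounts} (flexible residues per site, rotamer method),
#'   \code{siteCountsDchi} (delta-chi method), \code{truthCounts}.
#' @export
analyzeEnsemble <- function(ensemble, wall = FALSE, hbonds = FALSE,
                            tables = chemistryTables()) {
  recs <- list(); siteCounts <- integer(0); dchiCounts <- integer(0)
  truthCounts <- integer(0)
  for (j in seq_along(ensemble)) {
    g <- ensemble[[j]]
    pair <- asAcceptedPair(g$apo, g$holo, g$ligand,
                           pairID = sprintf("pair%04d", j))
    res <- analyzePair(pair, wall = wall, hbonds = hbonds, tables = tables)
    r <- res$residues
    r$pairID <- sprintf("pair%04d", j)
    recs[[j]] <- r
    siteCounts[j] <- sum(r$call == "flexible")
    dchiCounts[j] <- sum(r$deltaChi60)
    truthCounts[j] <- g$truth$siteFlexibleCount
  }
  list(records = do.call(rbind, recs), siteCounts = siteCounts,
       siteCountsDchi = dchiCounts, truthCounts = truthCounts)
}

#' Write the report tables of an ensemble analysis
#'
#' Emits deterministic TSV tables (fixed column order, fixed 4-decimal
#' formatting) so that identical analyses produce byte-identical files.
#'
#' @param analysis result of \code{\link{analyzeEnsemble}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReportTables <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.4f", x) else as.character(x)
  }
  paths <- character(0)
  rec <- analysis$records
  recOut <- as.data.frame(lapply(rec, fmt), stringsAsFactors = FALSE)
  p1 <- file.path(dir, "residue_records.tsv")
  utils::write.table(recOut, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  h <- siteChangeDistribution(analysis$siteCounts, "rotamer")
  p2 <- file.path(dir, "site_change_histogram.tsv")
  utils::write.table(
    data.frame(changes = names(h$histogram), sites = as.integer(h$histogram),
               cumulative = sprintf("%.6f", h$cumulative)),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- flexibilityScale(data.frame(type = rec$type, call = rec$call))
  p3 <- file.path(dir, "flexibility_scale.tsv")
  utils::write.table(
    data.frame(res_type = sc$res_type, nR = sc$nR, nT = sc$nT,
               P = sprintf("%.6f", sc$P), error = sprintf("%.6f", sc$error)),
    p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
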
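#' @include rotamer.R steric.R
NULL

#' Distribution of per-site conformational-change counts
#'
#' Histogram over binding sites of the number of residues called flexible
#' (rotamer method) or changed (delta-chi threshold method), with the
#' cumulative site fraction.
#'
#' @param counts integer vector: flexible-residue count per site.
#' @param method label carried through ("rotamer" or "delta_chi_60").
#' @return list with \code{method}, \code{histogram} (named integer vector
#'   over 0..max), \code{cumulative} (fractions), \code{nSites}.
#' @export
siteChangeDistribution <- function(counts, method = "rotamer") {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  bins <- 0:max(counts)
  h <- vapply(bins, function(b) sum(counts == b), integer(1))
  names(h) <- bins
  list(method = method, histogram = h,
       cumulative = cumsum(h) / sum(h), nSites = length(counts))
}

#' Correlation of the flexibility scale with an entropy table
#'
#' Pearson correlation between per-type flexibility probabilities and
#' side-chain configurational entropy differences, over the residue types
#' present in both tables.
#'
#' @param scale data.frame with columns res_type and P (as from
#'   \code{\link{flexibilityScale}}).
#' @param dS data.frame with columns res_type and delta_s, or a path to a
#'   2-column TSV.
#' @return list with \code{r}, \code{n} (types used) and the merged table.
#' @export
entropyCorrelation <- function(scale, dS) {
  if (is.character(dS))
    dS <- utils::read.table(dS, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
  m <- merge(scale, dS, by = "res_type")
  if (nrow(m) < 3) stop("fewer than 3 residue types overlap the entropy table")
  list(r = stats::cor(m$P, m$delta_s, method = "pearson"), n = nrow(m),
       table = m)
}

#' Compare B-factors and normalized SAS between flexible and rigid residues
#'
#' Two-sided Welch t-tests of Apo-form B-factors and normalized solvent
#' accessibilities, flexible versus rigid.  Groups smaller than 2 yield an
#' undefined comparison rather than an error.
#'
#' @param records data.frame with columns call ("flexible"/"rigid") and any
#'   of bfactor, normSAS.
#' @return data.frame: quantity, meanFlexible, meanRigid, t, p, nFlexible,
#'   nRigid, defined.
#' @export
compareFlexibleVsRigid <- function(records) {
  out <- list()
  for (q in intersect(c("bfactor", "normSAS"), names(records))) {
    f <- records[[q]][records$call == "flexible"]
    r <- records[[q]][records$call == "rigid"]
    f <- f[is.finite(f)]; r <- r[is.finite(r)]
    if (length(f) >= 2 && length(r) >= 2) {
      tt <- stats::t.test(f, r, var.equal = FALSE)
      out[[q]] <- data.frame(quantity = q, meanFlexible = mean(f),
                             meanRigid = mean(r),
                             t = unname(tt$statistic), p = tt$p.value,
                             nFlexible = length(f), nRigid = length(r),
                             defined = TRUE)
    } else {
      out[[q]] <- data.frame(quantity = q, meanFlexible = NA_real_,
                             meanRigid = NA_real_, t = NA_real_,
                             p = NA_real_, nFlexible = length(f),
                             nRigid = length(r), defined = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-form non-rotameric counts
#'
#' @param assignments data.frame with logical columns apoNR and holoNR.
#' @return list with \code{apo} and \code{holo} NR counts.
#' @export
nrCountComparison <- function(assignments) {
  list(apo = sum(assignments$apoNR), holo = sum(assignments$holoNR))
}

#' Minimal-rotation accounting over critical residues
#'
#' Of the residues whose movements are sterically critical, how many moved by
#' less than 15 degrees in every chi (the minimal-rotation regime)?
#'
#' @param records data.frame with columns critical (logical),
#'   minimalRotation (logical) and optionally call.
#' @return list with \code{nCritical}, \code{nMinimal}, \code{fraction}
#'   (NA when no residue is critical) and per-call splits when calls are
#'   present.
#' @export
minimalRotationSummary <- function(records) {
  crit <- records[records$critical %in% TRUE, , drop = FALSE]
  n <- nrow(crit)
  m <- sum(crit$minimalRotation %in% TRUE)
  out <- list(nCritical = n, nMinimal = m,
              fraction = if (n > 0) m / n else NA_real_)
  if ("call" %in% names(crit) && n > 0) {
    out$byCall <- table(call = crit$call,
                        minimal = crit$minimalRotation %in% TRUE)
  }
  out
}

#' Per-type flexibility probability scale
#'
#' Aggregates flexibility calls into the per-residue-type probability of
#' undergoing a rotamer change upon binding, with binomial errors, sorted by
#' decreasing probability.  Gly, Ala and Pro never appear (no analyzable chi
#' or backbone-coupled movement); excluded observations (both forms NR, or
#' failing the quality filter) are not counted.
#'
#' @param calls data.frame with columns type and call.
#' @return data.frame: res_type, nR, nT, P, error.
#' @export
flexibilityScale <- function(calls) {
  keep <- calls$call %in% c("flexible", "rigid") &
    !calls$type %in% c("GLY", "ALA", "PRO")
  calls <- calls[keep, , drop = FALSE]
  types <- sort(unique(calls$type))
  rows <- lapply(types, function(t) {
    nT <- sum(calls$type == t)
    nR <- sum(calls$type == t & calls$call == "flexible")
    pe <- flexibilityProbability(nR, nT)
    data.frame(res_type = t, nR = nR, nT = nT, P = pe$P, error = pe$error)
  })
  out <- do.call(rbind, rows)
  out[order(-out$P, out$res_type), ]
}

## reference side-chain SASA per residue type: the isolated residue built at
## its most frequent rotamer, computed with the package's own SASA engine so
## that normalized values are internally consistent
.refSasaCache <- new.env(parent = emptyenv())

referenceSideChainSASA <- function(type, tables = chemistryTables()) {
  type <- toupper(type)
  if (!is.null(.refSasaCache[[type]])) return(.refSasaCache[[type]])
  lib <- tables@rotamerLibrary
  rots <- .rotamersByFreq(type, lib)
  chis <- if (nrow(rots)) .rotamerChis(rots[1, ]) else numeric(0)
  df <- .residueDF(type, chis, c(0, 0, 0), c(0, 0, 1), 1)
  s <- sasa(df, tables = tables)
  sc <- !df$name %in% c("N", "CA", "C", "O", "OXT")
  val <- sum(s$perAtom[sc])
  .refSasaCache[[type]] <- val
  val
}

#' Normalized side-chain solvent accessibility
#'
#' Side-chain SASA of a residue in its structural context divided by the
#' same side chain's SASA in an isolated reference residue computed with the
#' same engine.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param keys residue keys to evaluate.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return named numeric vector of normalized SAS values in [0, 1]-ish range.
#' @export
normalizedSideChainSASA <- function(model, keys, tables = chemistryTables()) {
  prot <- model@atoms[model@atoms$category != "water" &
                      model@atoms$element != "H", , drop = FALSE]
  s <- sasa(prot, tables = tables)
  allKeys <- resKey(prot)
  out <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    sel <- allKeys == k & !prot$name %in% c("N", "CA", "C", "O", "OXT") &
      prot$category == "protein"
    type <- prot$resname[allKeys == k][1]
    ref <- referenceSideChainSASA(type, tables)
    out[[k]] <- if (ref > 0) sum(s$perAtom[sel]) / ref else NA_real_
  }
  out
}
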
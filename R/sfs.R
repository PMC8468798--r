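#' Construct a one-dimensional SFS
#'
#' @param entries numeric vector of length `n + 1` (counts indexed by allele
#'   copy number 0..n).
#' @param folded logical fold state.
#' @param mask logical vector parallel to `entries`; defaults to all
#'   unmasked.
#' @param L total callable sequence length in bp.
#' @return an [Sfs1D-class] object.
#' @export
Sfs1D <- function(entries, folded = FALSE, mask = NULL, L = NA_real_) {
  n <- length(entries) - 1L
  if (is.null(mask)) mask <- rep(FALSE, n + 1L)
  new("Sfs1D", entries = as.numeric(entries), n = as.integer(n),
      folded = folded, mask = mask, L = as.numeric(L))
}

#' Construct a joint two-population SFS
#'
#' @param entries numeric matrix `(n1 + 1) x (n2 + 1)`.
#' @param folded logical fold state.
#' @param mask logical matrix parallel to `entries`.
#' @param L total callable sequence length in bp.
#' @return an [Sfs2D-class] object.
#' @export
Sfs2D <- function(entries, folded = FALSE, mask = NULL, L = NA_real_) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "double"
  if (is.null(mask)) mask <- matrix(FALSE, nrow(entries), ncol(entries))
  new("Sfs2D", entries = entries, n1 = nrow(entries) - 1L,
      n2 = ncol(entries) - 1L, folded = folded, mask = mask,
      L = as.numeric(L))
}

setMethod("sfsEntries", "Sfs1D", function(sfs) sfs@entries)
setMethod("sfsEntries", "Sfs2D", function(sfs) sfs@entries)
setMethod("sfsMask", "Sfs1D", function(sfs) sfs@mask)
setMethod("sfsMask", "Sfs2D", function(sfs) sfs@mask)
setMethod("isFolded", "Sfs1D", function(sfs) sfs@folded)
setMethod("isFolded", "Sfs2D", function(sfs) sfs@folded)
setMethod("seqLength", "Sfs1D", function(sfs) sfs@L)
setMethod("seqLength", "Sfs2D", function(sfs) sfs@L)
setReplaceMethod("seqLength", "Sfs1D", function(sfs, value) {
  sfs@L <- as.numeric(value); sfs
})
setReplaceMethod("seqLength", "Sfs2D", function(sfs, value) {
  sfs@L <- as.numeric(value); sfs
})

#' @describeIn Sfs1D-class haploid sample size(s)
#' @export
setGeneric("sampleSizes", function(sfs) standardGeneric("sampleSizes"))
setMethod("sampleSizes", "Sfs1D", function(sfs) sfs@n)
setMethod("sampleSizes", "Sfs2D", function(sfs) c(sfs@n1, sfs@n2))

setMethod("show", "Sfs1D", function(object) {
  cat(sprintf("Sfs1D: n = %d, %s, S = %.6g, %d masked entries, L = %s\n",
              object@n, if (object@folded) "folded" else "unfolded",
              sum(object@entries[!object@mask]), sum(object@mask),
              format(object@L)))
})

setMethod("show", "Sfs2D", function(object) {
  cat(sprintf("Sfs2D: n1 = %d, n2 = %d, %s, S = %.6g, %d masked cells\n",
              object@n1, object@n2,
              if (object@folded) "folded" else "unfolded",
              sum(object@entries[!object@mask]), sum(object@mask)))
})

setMethod("fold", "Sfs1D", function(sfs) {
  if (sfs@folded) {
    warning("spectrum is already folded; returning unchanged")
    return(sfs)
  }
  n <- sfs@n
  e <- sfs@entries
  m <- sfs@mask
  half <- floor(n / 2)
  out <- numeric(n + 1L)
  outm <- rep(FALSE, n + 1L)
  for (i in 0:half) {
    j <- n - i
    if (j == i) {
      out[i + 1L] <- e[i + 1L]
      outm[i + 1L] <- m[i + 1L]
    } else {
      out[i + 1L] <- e[i + 1L] + e[j + 1L]
      outm[i + 1L] <- m[i + 1L] | m[j + 1L]
    }
  }
  new("Sfs1D", entries = out, n = n, folded = TRUE, mask = outm, L = sfs@L)
})

setMethod("fold", "Sfs2D", function(sfs) {
  if (sfs@folded) {
    warning("spectrum is already folded; returning unchanged")
    return(sfs)
  }
  n1 <- sfs@n1; n2 <- sfs@n2
  ntot <- n1 + n2
  e <- sfs@entries
  m <- sfs@mask
  out <- matrix(0, n1 + 1L, n2 + 1L)
  outm <- matrix(FALSE, n1 + 1L, n2 + 1L)
  for (i in 0:n1) {
    for (j in 0:n2) {
      ic <- n1 - i; jc <- n2 - j
      tot <- i + j
      # canonical representative: smaller total count; ties broken toward
      # the lexicographically smaller cell so each pair is aggregated once
      keep <- (2L * tot < ntot) ||
        (2L * tot == ntot && (i < ic || (i == ic && j <= jc)))
      if (!keep) next
      if (i == ic && j == jc) {
        out[i + 1L, j + 1L] <- e[i + 1L, j + 1L]
        outm[i + 1L, j + 1L] <- m[i + 1L, j + 1L]
      } else {
        out[i + 1L, j + 1L] <- e[i + 1L, j + 1L] + e[ic + 1L, jc + 1L]
        outm[i + 1L, j + 1L] <- m[i + 1L, j + 1L] | m[ic + 1L, jc + 1L]
      }
    }
  }
  new("Sfs2D", entries = out, n1 = n1, n2 = n2, folded = TRUE, mask = outm,
      L = sfs@L)
})

setMethod("applyMask", "Sfs1D", function(sfs, rule = "singletons_and_full") {
  if (!identical(rule, "singletons_and_full"))
    stop("unknown masking rule: ", rule)
  n <- sfs@n
  idx <- 0:n
  if (sfs@folded) {
    add <- idx <= 1L
  } else {
    add <- idx <= 1L | idx >= n - 1L
  }
  sfs@mask <- sfs@mask | add
  sfs
})

setMethod("applyMask", "Sfs2D", function(sfs, rule = "singletons_and_full") {
  if (!identical(rule, "singletons_and_full"))
    stop("unknown masking rule: ", rule)
  n1 <- sfs@n1; n2 <- sfs@n2
  tot <- outer(0:n1, 0:n2, "+")
  if (sfs@folded) {
    add <- tot <= 1L
  } else {
    add <- tot <= 1L | tot >= n1 + n2 - 1L
  }
  sfs@mask <- sfs@mask | add
  sfs
})

## hypergeometric projection weights: a site with ma called alleles of which
## x are alternate contributes dhyper(0:np, x, ma - x, np) to classes 0..np
.projectSite <- function(x, ma, np) dhyper(0:np, x, ma - x, np)

#' Build a 1D site-frequency spectrum from a genotype matrix
#'
#' Alternate-allele counts are tallied per site over the requested samples.
#' Sites with missing calls are hypergeometrically projected down to
#' `projectionN` haploid copies when given (every subsample of the called
#' alleles contributes its expected weight); otherwise sites with any
#' missing call are dropped.  `L` is set to the number of sites that
#' contributed.
#'
#' @param gm a [GenotypeMatrix-class] (biallelic sites; others are skipped).
#' @param samples optional character/integer subset of samples.
#' @param projectionN optional haploid size to project down to.
#' @return an unfolded [Sfs1D-class].
#' @export
buildSfs1d <- function(gm, samples = NULL, projectionN = NULL) {
  if (!is.null(samples)) gm <- gm[, samples]
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  nmax <- 2L * ncol(gm)
  if (nmax < 2L) stop("need at least 2 haploid samples after subsetting")
  called <- !is.na(g1) & !is.na(g2)
  biall <- rowData(gm)$alt != "" & (is.na(rowData(gm)$alt2) |
                                      rowData(gm)$alt2 == "")
  ma <- 2L * rowSums(called)
  x <- rowSums((g1 == 1L) * called, na.rm = TRUE) +
    rowSums((g2 == 1L) * called, na.rm = TRUE)
  if (is.null(projectionN)) {
    use <- biall & ma == nmax
    ent <- numeric(nmax + 1L)
    tab <- tabulate(x[use] + 1L, nbins = nmax + 1L)
    ent <- ent + tab
    L <- sum(use)
    return(Sfs1D(ent, L = L))
  }
  np <- as.integer(projectionN)
  use <- biall & ma >= np
  if (!any(use)) stop("projectionN exceeds the available alleles at all sites")
  ent <- numeric(np + 1L)
  for (s in which(use)) ent <- ent + .projectSite(x[s], ma[s], np)
  out <- Sfs1D(ent, L = sum(use))
  out
}

#' Build a joint 2D site-frequency spectrum from a genotype matrix
#'
#' @param gm a [GenotypeMatrix-class].
#' @param samples1,samples2 sample subsets defining the two populations.
#' @param projectionN optional length-2 integer vector of haploid sizes to
#'   project each population down to (independent hypergeometric
#'   projections).
#' @return an unfolded [Sfs2D-class].
#' @export
buildSfs2d <- function(gm, samples1, samples2, projectionN = NULL) {
  g1a <- SummarizedExperiment::assay(gm[, samples1], "GT1")
  g2a <- SummarizedExperiment::assay(gm[, samples1], "GT2")
  g1b <- SummarizedExperiment::assay(gm[, samples2], "GT1")
  g2b <- SummarizedExperiment::assay(gm[, samples2], "GT2")
  biall <- rowData(gm)$alt != "" & (is.na(rowData(gm)$alt2) |
                                      rowData(gm)$alt2 == "")
  ca <- !is.na(g1a) & !is.na(g2a)
  cb <- !is.na(g1b) & !is.na(g2b)
  maA <- 2L * rowSums(ca); maB <- 2L * rowSums(cb)
  xA <- rowSums((g1a == 1L) * ca, na.rm = TRUE) +
    rowSums((g2a == 1L) * ca, na.rm = TRUE)
  xB <- rowSums((g1b == 1L) * cb, na.rm = TRUE) +
    rowSums((g2b == 1L) * cb, na.rm = TRUE)
  n1max <- 2L * ncol(g1a); n2max <- 2L * ncol(g1b)
  if (is.null(projectionN)) {
    use <- biall & maA == n1max & maB == n2max
    ent <- matrix(0, n1max + 1L, n2max + 1L)
    for (s in which(use)) ent[xA[s] + 1L, xB[s] + 1L] <-
        ent[xA[s] + 1L, xB[s] + 1L] + 1
    return(Sfs2D(ent, L = sum(use)))
  }
  np <- as.integer(projectionN)
  use <- biall & maA >= np[1] & maB >= np[2]
  if (!any(use)) stop("projectionN exceeds the available alleles at all sites")
  ent <- matrix(0, np[1] + 1L, np[2] + 1L)
  for (s in which(use)) {
    wa <- .projectSite(xA[s], maA[s], np[1])
    wb <- .projectSite(xB[s], maB[s], np[2])
    ent <- ent + outer(wa, wb)
  }
  Sfs2D(ent, L = sum(use))
}

#' Write / read an SFS in dadi-style whitespace text
#'
#' Three content lines: a header with the array extents (`n + 1` per
#' dimension) and the fold state, the entries, and a 0/1 mask row (1 =
#' masked).  2D entries are written row by row (population 1 index slowest).
#' A leading comment line records `L`; integer entries round-trip exactly.
#'
#' @param sfs an [Sfs1D-class] or [Sfs2D-class].
#' @param path file path.
#' @return `writeSfs` returns `path` invisibly; `readSfs` returns the
#'   spectrum.
#' @export
writeSfs <- function(sfs, path) {
  ent <- sfsEntries(sfs)
  msk <- sfsMask(sfs)
  dims <- if (is(sfs, "Sfs2D")) c(sfs@n1 + 1L, sfs@n2 + 1L) else sfs@n + 1L
  lines <- c(
    sprintf("# coalstep SFS L=%s", format(seqLength(sfs), digits = 17)),
    paste(c(dims, if (isFolded(sfs)) "folded" else "unfolded"),
          collapse = " "),
    paste(format(as.vector(if (is.matrix(ent)) t(ent) else ent),
                 digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "),
    paste(as.integer(as.vector(if (is.matrix(msk)) t(msk) else msk)),
          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSfs
#' @export
readSfs <- function(path) {
  lines <- readLines(path)
  L <- NA_real_
  cm <- grepl("^#", lines)
  lt <- lines[cm]
  if (length(lt) && grepl("L=", lt[1]))
    L <- suppressWarnings(as.numeric(sub(".*L=", "", lt[1])))
  lines <- lines[!cm & nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed SFS file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  folded <- identical(hdr[length(hdr)], "folded")
  dims <- as.integer(hdr[-length(hdr)])
  ent <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  msk <- as.logical(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]]))
  if (length(dims) == 1L) {
    Sfs1D(ent, folded = folded, mask = msk, L = L)
  } else {
    e <- matrix(ent, dims[1], dims[2], byrow = TRUE)
    m <- matrix(msk, dims[1], dims[2], byrow = TRUE)
    Sfs2D(e, folded = folded, mask = m, L = L)
  }
}
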
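#' Exact conditional Hardy-Weinberg test
#'
#' Two-sided exact test of Hardy-Weinberg genotype proportions, conditional
#' on the observed allele counts: the p-value is the total probability of
#' all heterozygote counts whose conditional probability does not exceed
#' that of the observed count (no mid-p correction).  A chi-square
#' alternative is available for large samples.
#'
#' @param nAA,nAa,naa genotype counts (hom-ref, het, hom-alt).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return the p-value; `NA` when fewer than 2 genotypes are observed or
#'   the site is monomorphic.
#' @examples
#' hweExactP(25, 50, 25)   # perfect proportions, p ~ 1
#' hweExactP(50, 0, 50)    # total heterozygote deficit, p << 1e-6
#' @export
hweExactP <- function(nAA, nAa, naa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  n <- nAA + nAa + naa
  if (n < 2L) return(NA_real_)
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0L || na == 0L) return(NA_real_)
  if (method == "chisq") {
    p <- nA / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(nAA, nAa, naa) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  nr <- min(nA, na)
  hs <- seq.int(nr %% 2L, nr, by = 2L)
  # log P(nAa = h | n, nr) up to a common constant
  lp <- vapply(hs, function(h) {
    hom1 <- (nr - h) / 2
    hom2 <- (2L * n - nr - h) / 2
    h * log(2) + lgamma(n + 1) -
      (lgamma(hom1 + 1) + lgamma(h + 1) + lgamma(hom2 + 1))
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hs)]
  sum(pr[pr <= pObs * (1 + 1e-12)])
}
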
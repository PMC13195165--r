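#' Chromosome arm label sets
#'
#' The diploid human genome carries 92 telomeric sites (22 autosomal pairs
#' x 4 arm copies + 4 sex-chromosome arms). After collapsing the two
#' homologous copies, up to 48 arm labels remain per person. Analyses of
#' telomere length drop the acrocentric short arms (13p, 14p, 15p, 21p,
#' 22p), whose pseudo-homologous regions prevent unambiguous assignment,
#' and the sex-chromosome arms, leaving 39 autosomal arms.
#'
#' @return \code{arm_labels} returns the 48 collapsed arm labels in
#'   karyotype order; \code{analysis_arms} the 39 autosomal arms retained
#'   for association analyses; \code{acrocentric_p_arms} and
#'   \code{sex_chromosome_arms} the excluded subsets.
#' @examples
#' length(arm_labels())     # 48
#' length(analysis_arms())  # 39
#' @export
arm_labels <- function() {
  auto <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  c(auto, "Xp", "Xq", "Yp", "Yq")
}

#' @rdname arm_labels
#' @export
acrocentric_p_arms <- function() c("13p", "14p", "15p", "21p", "22p")

#' @rdname arm_labels
#' @export
sex_chromosome_arms <- function() c("Xp", "Xq", "Yp", "Yq")

#' @rdname arm_labels
#' @export
analysis_arms <- function() {
  setdiff(arm_labels(), c(acrocentric_p_arms(), sex_chromosome_arms()))
}

#' Default arm mean telomere-length profile
#'
#' A fixed 48-arm profile spanning 2--6 kb that encodes the field's
#' reported ordering of arm mean telomere lengths: 3p, 4q and 13q among
#' the longest, and 3q, 16q, 20q, 17p and 12p among the shortest. The
#' profile supplies relative ordering only; \code{\link{make_cohort}}
#' rescales its deviations so the configured arm variance fraction is met
#' exactly across the 39 analysis arms.
#'
#' @return Named numeric vector of length 48 (bp).
#' @export
default_arm_profile <- function() {
  arms <- arm_labels()
  long_arms <- c("3p", "4q", "13q")
  short_arms <- c("3q", "16q", "20q", "17p", "12p")
  middle <- setdiff(arms, c(long_arms, short_arms))
  ordering <- c(long_arms, middle, short_arms)
  prof <- seq(6000, 2000, length.out = length(ordering))
  names(prof) <- ordering
  prof[arms]
}
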
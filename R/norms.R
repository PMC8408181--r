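# Social norms: assessment rule + action rule + generosity parameters.
#
# Reputations are binary labels "G" (good) and "B" (bad).  An assessment rule
# maps (observed action, donor reputation, recipient reputation) to the
# probability of assigning a good reputation (8 entries); an action rule maps
# (donor's self-reputation, recipient reputation) to the probability of
# cooperating (4 entries).  "Good" is the label that makes receiving
# cooperation more likely under the leading-eight action rules.

.ASSESS_CONTEXTS <- c("C:GG", "C:GB", "C:BG", "C:BB",
                      "D:GG", "D:GB", "D:BG", "D:BB")
.ACTION_CONTEXTS <- c("GG", "GB", "BG", "BB")

# All leading-eight norms share: cooperation with a good recipient is assessed
# good, defection against a good recipient bad, defection by a good donor
# against a bad recipient good (justified punishment); the action rule
# cooperates with good recipients and defects when a good donor faces a bad
# recipient.  They differ only in the bad-recipient degrees of freedom
# assessment(C,G,B), assessment(C,B,B), assessment(D,B,B) and action(B,B);
# within the set, action(B,B) prescribes cooperation exactly where
# assessment(C,B,B) = G, and norms come in pairs differing only in
# assessment(C,G,B).  The free entries below are indexed L1..L8; L3 is
# Simple Standing, L6 is Stern Judging.
.L_FREE <- matrix(c(
  # C:GB  C:BB  D:BB  act:BB
      1,    1,    0,    1,   # L1
      0,    1,    0,    1,   # L2  (Consistent Standing)
      1,    1,    1,    1,   # L3  (Simple Standing)
      0,    1,    1,    1,   # L4
      1,    0,    1,    0,   # L5
      0,    0,    1,    0,   # L6  (Stern Judging)
      1,    0,    0,    0,   # L7
      0,    0,    0,    0    # L8
), ncol = 4, byrow = TRUE,
  dimnames = list(paste0("L", 1:8), c("C:GB", "C:BB", "D:BB", "BB")))

new_social_norm <- function(name, assessment, action, g1 = 0, g2 = 0) {
  stopifnot(length(assessment) == 8, length(action) == 4)
  assessment <- stats::setNames(as.numeric(assessment), .ASSESS_CONTEXTS)
  action <- stats::setNames(as.numeric(action), .ACTION_CONTEXTS)
  if (any(assessment < 0 | assessment > 1) || any(action < 0 | action > 1))
    stop("norm entries must be probabilities in [0, 1]", call. = FALSE)
  structure(list(name = name, assessment = assessment, action = action,
                 g1 = g1, g2 = g2),
            class = "social_norm")
}

#' Leading-eight social norms
#'
#' Returns one of the eight deterministic third-order social norms that
#' sustain cooperation by indirect reciprocity under public information.
#' Each norm consists of an assessment rule (probability of assigning a good
#' reputation, given the observed action and the reputations of donor and
#' recipient) and an action rule (probability of cooperating, given the
#' donor's self-reputation and the recipient's reputation).  All eight norms
#' reward cooperation with a good recipient and condemn defection against a
#' good recipient; they differ only in how they treat interactions with a bad
#' recipient.  \code{L6} is Stern Judging; \code{L2} is consistent standing.
#'
#' @param index integer between 1 and 8.
#' @return A \code{social_norm} object with \code{g1 = g2 = 0}.
#' @seealso [make_generous()], [allc()], [alld()]
#' @examples
#' leading_eight(1)
#' leading_eight(6)$assessment  # Stern Judging
#' @export
leading_eight <- function(index) {
  if (length(index) != 1 || is.na(index) || index != as.integer(index) ||
      index < 1 || index > 8)
    stop("index must be a single integer in 1..8", call. = FALSE)
  index <- as.integer(index)
  free <- .L_FREE[index, ]
  assessment <- c("C:GG" = 1, "C:GB" = free[["C:GB"]], "C:BG" = 1,
                  "C:BB" = free[["C:BB"]],
                  "D:GG" = 0, "D:GB" = 1, "D:BG" = 0,
                  "D:BB" = free[["D:BB"]])
  action <- c("GG" = 1, "GB" = 0, "BG" = 1, "BB" = free[["BB"]])
  new_social_norm(paste0("L", index), assessment, action)
}

#' Unconditional cooperation and defection
#'
#' \code{allc()} assigns a good reputation to all behaviors and cooperates
#' with everyone; \code{alld()} uniformly assigns bad reputations and always
#' defects.  Generosity never applies to these norms.
#'
#' @return A \code{social_norm} object.
#' @export
allc <- function() new_social_norm("ALLC", rep(1, 8), rep(1, 4))

#' @rdname allc
#' @export
alld <- function() new_social_norm("ALLD", rep(0, 8), rep(0, 4))

#' Add assessment and action generosity to a leading-eight norm
#'
#' Every assessment entry in which the deterministic baseline assigns a bad
#' reputation (entry 0) is replaced by \code{g1}, the probability of
#' assessment generosity; every action entry in which the baseline defects is
#' replaced by \code{g2}, the probability of action generosity.  Entries equal
#' to 1 are never touched: players are forgiving but not spiteful.  A single
#' \code{g1} applies to all bad-assessment contexts and a single \code{g2} to
#' all defection contexts.  With \code{g1 = g2 = 0} the baseline norm is
#' recovered unchanged.
#'
#' @param base a deterministic leading-eight \code{social_norm}.
#' @param g1 probability of assigning a good reputation where the baseline
#'   assigns bad.
#' @param g2 probability of cooperating where the baseline defects.
#' @return A \code{social_norm} carrying the same name as \code{base}.
#' @examples
#' make_generous(leading_eight(6), 0.05, 0)$assessment[["C:GB"]]  # 0.05
#' @export
make_generous <- function(base, g1, g2) {
  stopifnot(inherits(base, "social_norm"))
  if (base$name %in% c("ALLC", "ALLD"))
    stop("generosity applies to leading-eight norms only", call. = FALSE)
  if (length(g1) != 1 || length(g2) != 1 || is.na(g1) || is.na(g2) ||
      g1 < 0 || g1 > 1 || g2 < 0 || g2 > 1)
    stop("g1 and g2 must be probabilities in [0, 1]", call. = FALSE)
  assessment <- ifelse(base$assessment == 0, g1, base$assessment)
  action <- ifelse(base$action == 0, g2, base$action)
  new_social_norm(base$name, assessment, action,
                  g1 = if (any(base$assessment == 0)) g1 else base$g1,
                  g2 = if (any(base$action == 0)) g2 else base$g2)
}

#' Look up norm probabilities
#'
#' \code{assessment_prob()} returns the probability that an observer using
#' \code{norm} assigns a good reputation after perceiving \code{action} by a
#' donor with reputation \code{donor} toward a recipient with reputation
#' \code{recipient}.  \code{action_prob()} returns the probability that a
#' donor using \code{norm} cooperates, given its self-reputation \code{self}
#' and the recipient's reputation.
#'
#' @param norm a \code{social_norm}.
#' @param action observed action, \code{"C"} or \code{"D"}.
#' @param donor,recipient,self reputation labels, \code{"G"} or \code{"B"}.
#' @return A probability.
#' @export
assessment_prob <- function(norm, action, donor, recipient) {
  stopifnot(inherits(norm, "social_norm"),
            action %in% c("C", "D"),
            donor %in% c("G", "B"), recipient %in% c("G", "B"))
  norm$assessment[[paste0(action, ":", donor, recipient)]]
}

#' @rdname assessment_prob
#' @export
action_prob <- function(norm, self, recipient) {
  stopifnot(inherits(norm, "social_norm"),
            self %in% c("G", "B"), recipient %in% c("G", "B"))
  norm$action[[paste0(self, recipient)]]
}

#' Draw a single assessment or action
#'
#' Bernoulli draws over the corresponding rule entry, using R's random number
#' stream.  Each call consumes exactly one uniform variate, so a fixed
#' \code{set.seed()} makes sequences of draws reproducible.
#'
#' @inheritParams assessment_prob
#' @return \code{sample_assessment()} returns \code{"G"} or \code{"B"};
#'   \code{sample_action()} returns \code{"C"} or \code{"D"}.
#' @export
sample_assessment <- function(norm, action, donor, recipient) {
  p <- assessment_prob(norm, action, donor, recipient)
  if (stats::runif(1) < p) "G" else "B"
}

#' @rdname sample_assessment
#' @export
sample_action <- function(norm, self, recipient) {
  p <- action_prob(norm, self, recipient)
  if (stats::runif(1) < p) "C" else "D"
}

#' Serialize a social norm to and from JSON
#'
#' The JSON object has fields \code{name}, \code{assessment} (8 probabilities
#' keyed by \code{"action,donor,recipient"}), \code{action} (4 probabilities
#' keyed by \code{"donor,recipient"}), \code{g1} and \code{g2}.
#'
#' @param norm a \code{social_norm}.
#' @param json a JSON string as produced by \code{norm_to_json()}.
#' @return \code{norm_to_json()} returns a JSON string; \code{norm_from_json()}
#'   returns a \code{social_norm}.
#' @export
norm_to_json <- function(norm) {
  stopifnot(inherits(norm, "social_norm"))
  akeys <- gsub(":", ",", gsub("(.)(.)$", "\\1,\\2", names(norm$assessment)))
  bkeys <- sub("(.)(.)", "\\1,\\2", names(norm$action))
  jsonlite::toJSON(list(
    name = norm$name,
    assessment = as.list(stats::setNames(norm$assessment, akeys)),
    action = as.list(stats::setNames(norm$action, bkeys)),
    g1 = norm$g1, g2 = norm$g2), auto_unbox = TRUE, digits = NA)
}

#' @rdname norm_to_json
#' @export
norm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  akeys <- vapply(strsplit(names(x$assessment), ","), function(p)
    paste0(p[1], ":", p[2], p[3]), "")
  bkeys <- vapply(strsplit(names(x$action), ","), function(p)
    paste0(p[1], p[2]), "")
  assessment <- unlist(x$assessment)[order(match(akeys, .ASSESS_CONTEXTS))]
  action <- unlist(x$action)[order(match(bkeys, .ACTION_CONTEXTS))]
  new_social_norm(x$name, assessment, action, g1 = x$g1, g2 = x$g2)
}

#' @export
print.social_norm <- function(x, ...) {
  cat("Social norm", x$name,
      sprintf("(g1 = %g, g2 = %g)\n", x$g1, x$g2))
  cat("  assessment (P[good]):\n")
  m <- matrix(x$assessment, nrow = 2, byrow = TRUE,
              dimnames = list(c("after C", "after D"),
                              c("GG", "GB", "BG", "BB")))
  print(m)
  cat("  action (P[cooperate]):\n")
  print(matrix(x$action, nrow = 1,
               dimnames = list("", c("GG", "GB", "BG", "BB"))))
  invisible(x)
}

# internal: 8- and 4-entry numeric rows in the column order used by the
# compiled simulator
.norm_rows <- function(norm) {
  list(assessment = unname(norm$assessment), action = unname(norm$action))
}
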
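#' Diagnostic pathway probability table
#'
#' Probabilities, by cancer status, of the nine observed sequences of clinic
#' diagnostic activities undertaken after initial assessment. The defaults are
#' the audit-derived proportions for a large UK symptomatic breast clinic:
#' most patients without cancer undergo ultrasound only or a
#' mammogram/ultrasound combination, while most patients with cancer undergo
#' the full triple assessment (mammogram, ultrasound, biopsy).
#'
#' Sequence labels that involve both imaging modalities ("mammogram and
#' ultrasound" vs "ultrasound and mammogram") are treated as the same activity
#' *set*; the modality order is resolved at sampling time by
#' `mammogram_first`, the clinic-wide probability that mammography precedes
#' ultrasound (default 60%).
#'
#' @param probs_noncancer,probs_cancer Numeric vectors of length 9, one
#'   probability per sequence label, each summing to 1 (tolerance `1e-6`).
#' @param mammogram_first Probability that, in sequences containing both
#'   imaging modalities, mammogram is performed first.
#' @param discharge_noncancer Probability that a patient without cancer is
#'   discharged directly after initial assessment (no imaging).
#'
#' @return A `clinic_pathway_table`: a tibble with one row per sequence label
#'   and columns `label`, `activities` (list column of activity names, order
#'   unresolved), `p_noncancer`, `p_cancer`; the order and discharge
#'   probabilities are attached as attributes.
#' @examples
#' pathway_table()
#' @export
pathway_table <- function(probs_noncancer = c(
                            0.012766, 0.272533, 0.035168, 0.394921,
                            0.181688, 0.023445, 0.060947, 0.017845, 0.000686
                          ),
                          probs_cancer = c(
                            0.005525, 0.038122, 0.510497, 0.013812,
                            0.025414, 0.340331, 0.035912, 0.027624, 0.002762
                          ),
                          mammogram_first = 0.60,
                          discharge_noncancer = 0.25) {
  stopifnot(
    length(probs_noncancer) == 9L, length(probs_cancer) == 9L,
    all(probs_noncancer >= 0), all(probs_cancer >= 0),
    all(probs_noncancer <= 1), all(probs_cancer <= 1)
  )
  # probabilities printed to 6 dp can each be off by 5e-7; allow that and
  # renormalise so the sampled distribution is exact
  if (abs(sum(probs_noncancer) - 1) > 5e-6) {
    abort("`probs_noncancer` must sum to 1 (6-dp rounding tolerance).")
  }
  if (abs(sum(probs_cancer) - 1) > 5e-6) {
    abort("`probs_cancer` must sum to 1 (6-dp rounding tolerance).")
  }
  probs_noncancer <- probs_noncancer / sum(probs_noncancer)
  probs_cancer <- probs_cancer / sum(probs_cancer)
  stopifnot(
    mammogram_first >= 0, mammogram_first <= 1,
    discharge_noncancer >= 0, discharge_noncancer <= 1
  )
  out <- tibble(
    label = c(
      "mammogram_only", "mammogram_ultrasound", "mammogram_ultrasound_biopsy",
      "ultrasound_only", "ultrasound_mammogram", "ultrasound_mammogram_biopsy",
      "ultrasound_biopsy", "biopsy_only", "mammogram_biopsy"
    ),
    activities = list(
      c("mammogram"), c("mammogram", "ultrasound"),
      c("mammogram", "ultrasound", "biopsy"),
      c("ultrasound"), c("ultrasound", "mammogram"),
      c("ultrasound", "mammogram", "biopsy"),
      c("ultrasound", "biopsy"), c("biopsy"), c("mammogram", "biopsy")
    ),
    p_noncancer = probs_noncancer,
    p_cancer = probs_cancer
  )
  structure(out,
    mammogram_first = mammogram_first,
    discharge_noncancer = discharge_noncancer,
    class = c("clinic_pathway_table", class(out))
  )
}

# Map a label index + resolved modality order to the integer activity codes
# used by the session engine (initial assessment prepended by the caller).
.label_activity_sets <- list(
  c(ACT_MAM),                     # 1 mammogram only
  c(ACT_MAM, ACT_US),             # 2 both imaging
  c(ACT_MAM, ACT_US, ACT_BIOPSY), # 3 both imaging + biopsy
  c(ACT_US),                      # 4 ultrasound only
  c(ACT_MAM, ACT_US),             # 5 both imaging (order re-resolved)
  c(ACT_MAM, ACT_US, ACT_BIOPSY), # 6 both imaging + biopsy
  c(ACT_US, ACT_BIOPSY),          # 7 ultrasound + biopsy
  c(ACT_BIOPSY),                  # 8 biopsy only
  c(ACT_MAM, ACT_BIOPSY)          # 9 mammogram + biopsy
)
.label_has_both <- c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)

#' Sample clinic diagnostic pathways
#'
#' Draws, for each patient, the ordered sequence of clinic activities they
#' will require. Every sequence starts with initial assessment. A patient
#' without cancer may be discharged directly after assessment; otherwise one
#' of the nine audit sequences is drawn from the relevant stratum. Every
#' patient with cancer requires a biopsy: if the drawn sequence lacks one, a
#' biopsy is appended (clinical-practice assumption). Sequences containing
#' both imaging modalities are ordered mammogram-first with probability
#' `attr(table, "mammogram_first")`.
#'
#' @param patients A data frame with a logical `has_cancer` column (e.g. from
#'   [assign_cancer()]).
#' @param table A [pathway_table()].
#' @return `patients` with added columns: `pathway_label` (drawn sequence
#'   label, `NA` for discharged patients), `discharged_after_assessment`, and
#'   `activity_seq` (list column of integer activity codes; see
#'   [activity_names()]).
#' @examples
#' set.seed(1)
#' pats <- assign_cancer(tibble::tibble(id = 1:8), prevalence = 0.5)
#' sample_clinic_pathway(pats)$activity_seq
#' @export
sample_clinic_pathway <- function(patients, table = pathway_table()) {
  stopifnot(is.data.frame(patients), "has_cancer" %in% names(patients))
  if (!inherits(table, "clinic_pathway_table")) {
    abort("`table` must be a `clinic_pathway_table` (see `pathway_table()`).")
  }
  n <- nrow(patients)
  has_cancer <- patients$has_cancer
  p_disch <- attr(table, "discharge_noncancer")
  p_mam_first <- attr(table, "mammogram_first")

  discharged <- !has_cancer & runif(n) < p_disch
  label <- rep(NA_integer_, n)
  draw <- !discharged
  if (any(draw & has_cancer)) {
    label[draw & has_cancer] <- sample.int(9L, sum(draw & has_cancer),
      replace = TRUE, prob = table$p_cancer
    )
  }
  if (any(draw & !has_cancer)) {
    label[draw & !has_cancer] <- sample.int(9L, sum(draw & !has_cancer),
      replace = TRUE, prob = table$p_noncancer
    )
  }
  mam_first <- runif(n) < p_mam_first

  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    if (discharged[i]) {
      seqs[[i]] <- ACT_IA
      next
    }
    acts <- .label_activity_sets[[label[i]]]
    if (.label_has_both[label[i]] && !mam_first[i]) {
      # swap the leading mammogram/ultrasound pair
      acts[1:2] <- acts[2:1]
    }
    if (has_cancer[i] && !(ACT_BIOPSY %in% acts)) {
      acts <- c(acts, ACT_BIOPSY)
    }
    seqs[[i]] <- c(ACT_IA, acts)
  }

  patients$pathway_label <- ifelse(is.na(label), NA_character_,
    table$label[pmax(label, 1L)]
  )
  patients$discharged_after_assessment <- discharged
  patients$activity_seq <- seqs
  as_tibble(patients)
}

#' Activity code labels
#'
#' @param codes Integer activity codes as stored in `activity_seq` columns.
#' @return Character vector of activity names.
#' @examples
#' activity_names(1:4)
#' @export
activity_names <- function(codes) ACT_LEVELS[codes]

#' Activity duration model
#'
#' Central service times (minutes) for each clinic activity, with a symmetric
#' triangular spread representing run-to-run variation. The triangular
#' distribution has the stated value as mode and `dispersion` relative
#' half-width (default 25%), so the median and mean equal the stated value and
#' samples stay positive and bounded. Biopsy is a two-point mixture (short or
#' long procedure, equally likely) with patient preparation already included;
#' mammogram and ultrasound have a separate preparation step of `prep`
#' minutes.
#'
#' @param initial_assessment,mammogram,ultrasound Central durations, minutes.
#' @param biopsy Numeric vector of length 2: short and long biopsy durations.
#' @param biopsy_long_prob Probability of the long biopsy.
#' @param dispersion Relative half-width of the triangular spread (0 gives
#'   degenerate, exact durations).
#' @param prep Imaging preparation duration, minutes (escort + positioning;
#'   held jointly with the imaging room).
#' @return A `clinic_duration_model` list.
#' @examples
#' duration_model(dispersion = 0)
#' @export
duration_model <- function(initial_assessment = 10, mammogram = 20,
                           ultrasound = 20, biopsy = c(30, 45),
                           biopsy_long_prob = 0.5,
                           dispersion = 0.25, prep = 5) {
  stopifnot(
    initial_assessment > 0, mammogram > 0, ultrasound > 0,
    length(biopsy) == 2L, all(biopsy > 0),
    biopsy_long_prob >= 0, biopsy_long_prob <= 1,
    dispersion >= 0, dispersion < 1, prep >= 0
  )
  structure(
    list(
      initial_assessment = initial_assessment, mammogram = mammogram,
      ultrasound = ultrasound, biopsy = as.numeric(biopsy),
      biopsy_long_prob = biopsy_long_prob,
      dispersion = dispersion, prep = prep
    ),
    class = "clinic_duration_model"
  )
}

# Symmetric triangular sample with mode m and half-width w*m.
.rtri <- function(n, m, w) {
  if (w == 0) {
    return(rep(m, n))
  }
  a <- m * (1 - w)
  b <- m * (1 + w)
  u <- runif(n)
  ifelse(u < 0.5,
    a + (b - a) * sqrt(u / 2),
    b - (b - a) * sqrt((1 - u) / 2)
  )
}

#' Sample activity durations
#'
#' @param activity Activity name (one of
#'   `"initial_assessment"`, `"mammogram"`, `"ultrasound"`, `"biopsy"`) or
#'   integer code.
#' @param model A [duration_model()].
#' @param n Number of samples.
#' @return Numeric vector of durations in minutes.
#' @examples
#' set.seed(1)
#' mean(sample_duration("biopsy", n = 1e4)) # ~ 37.5
#' @export
sample_duration <- function(activity, model = duration_model(), n = 1) {
  stopifnot(inherits(model, "clinic_duration_model"))
  if (is.character(activity)) {
    activity <- match(activity, ACT_LEVELS)
  }
  if (length(activity) != 1L || is.na(activity) ||
    !(activity %in% 1:4)) {
    abort("`activity` must be a single recognised clinic activity.")
  }
  if (activity == ACT_BIOPSY) {
    long <- runif(n) < model$biopsy_long_prob
    return(ifelse(long, model$biopsy[2], model$biopsy[1]))
  }
  m <- switch(activity, model$initial_assessment, model$mammogram,
    model$ultrasound
  )
  .rtri(n, m, model$dispersion)
}
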
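#' @keywords internal
"_PACKAGE"

#' @useDynLib carotidrf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats complete.cases cor cov dnorm pnorm qnorm quantile rbinom
#'   rnorm runif sd setNames shapiro.test t.test uniroot wilcox.test chisq.test
#'   predict
#' @importFrom utils read.csv write.csv head
NULL

# Canonical orderings used throughout the package ----------------------------

#' @rdname feature_names
#' @export
mri_parameters <- function() {
  c("CVR", "CBV", "OEF", "OEC", "CTH", "MTT", "TTP", "CBF")
}

.tissues <- c("GM", "WM")
.zones <- c("inside", "outside")
.hemis <- c("ipsi", "contra")

# Fixed (tissue, zone) display order: GM inside, GM outside, WM inside, WM outside
.tissue_zone <- data.frame(
  tissue = c("GM", "GM", "WM", "WM"),
  zone = c("inside", "outside", "inside", "outside"),
  stringsAsFactors = FALSE
)

#' mq-BOLD susceptibility scaling constant at 3 Tesla
#'
#' The constant `c = 4/3 * pi * gamma * delta-chi * B0` relating the
#' reversible relaxation rate R2' to relative oxygen extraction via
#' `rOEF = R2' / (c * rCBV)`. At 3 T its value is 317 Hz; the gyromagnetic
#' ratio and the susceptibility difference between fully oxygenated and
#' deoxygenated blood are folded into the single stored constant.
#'
#' @return Scalar, Hz.
#' @export
mqbold_constant <- function() 317

# Group parameter table (means +/- SD per VOI) --------------------------------

# Per parameter: rows ipsi, contra; columns = ICAS GMin, GMout, WMin, WMout,
# then HC GMin, GMout, WMin, WMout, as (mean, sd) pairs.
.param_values <- list(
  CVR = list(
    ipsi   = c(20.2, 6.2, 23.7, 5.3, 12.0, 4.8, 16.5, 4.5,
               29.3, 5.8, 31.1, 5.0, 16.0, 3.1, 21.3, 3.7),
    contra = c(23.0, 6.5, 25.1, 5.2, 15.3, 5.0, 18.3, 4.8,
               29.1, 5.8, 29.0, 5.5, 16.9, 4.7, 20.2, 4.9)),
  CBV = list(
    ipsi   = c(4.43, 0.36, 5.13, 0.42, 2.62, 0.16, 3.18, 0.14,
               4.57, 0.45, 5.26, 0.26, 2.47, 0.08, 3.24, 0.14),
    contra = c(4.23, 0.38, 4.98, 0.37, 2.47, 0.10, 3.08, 0.15,
               4.59, 0.37, 5.20, 0.26, 2.47, 0.08, 3.15, 0.10)),
  OEF = list(
    ipsi   = c(0.56, 0.06, 0.62, 0.05, 0.94, 0.10, 0.92, 0.09,
               0.58, 0.08, 0.64, 0.06, 1.02, 0.10, 0.95, 0.08),
    contra = c(0.57, 0.06, 0.63, 0.06, 0.98, 0.09, 0.93, 0.08,
               0.58, 0.05, 0.63, 0.06, 1.00, 0.09, 0.95, 0.07)),
  OEC = list(
    ipsi   = c(0.38, 0.08, 0.33, 0.09, 0.44, 0.07, 0.37, 0.08,
               0.38, 0.07, 0.35, 0.07, 0.44, 0.07, 0.38, 0.07),
    contra = c(0.34, 0.10, 0.30, 0.09, 0.39, 0.09, 0.33, 0.10,
               0.38, 0.07, 0.33, 0.08, 0.42, 0.07, 0.36, 0.08)),
  CTH = list(
    ipsi   = c(3.03, 1.34, 2.86, 1.25, 3.81, 1.70, 3.17, 1.33,
               2.81, 0.95, 2.88, 0.93, 3.48, 1.11, 3.09, 1.04),
    contra = c(2.54, 1.23, 2.45, 1.21, 3.25, 1.44, 2.70, 1.24,
               2.75, 0.94, 2.75, 0.93, 3.41, 1.20, 2.94, 1.04)),
  MTT = list(
    ipsi   = c(2.54, 0.92, 2.28, 0.92, 3.17, 1.01, 2.57, 0.91,
               2.46, 0.71, 2.34, 0.68, 3.04, 0.81, 2.54, 0.75),
    contra = c(2.12, 0.92, 1.93, 0.90, 2.69, 1.03, 2.17, 0.92,
               2.39, 0.68, 2.21, 0.69, 2.93, 0.84, 2.40, 0.77)),
  TTP = list(
    ipsi   = c(12.3, 1.3, 11.7, 1.4, 12.8, 1.4, 12.1, 1.3,
               12.1, 1.3, 11.6, 1.3, 12.6, 1.4, 11.9, 1.3),
    contra = c(11.7, 1.4, 11.2, 1.3, 12.3, 1.3, 11.6, 1.3,
               12.0, 1.4, 11.5, 1.3, 12.6, 1.4, 11.8, 1.4)),
  CBF = list(
    ipsi   = c(25.3, 6.9, 25.6, 5.9, 17.5, 5.3, 23.6, 5.6,
               27.3, 6.1, 26.6, 5.1, 19.3, 4.7, 24.6, 4.8),
    contra = c(30.3, 6.8, 28.8, 6.0, 22.1, 5.5, 27.2, 5.8,
               28.0, 6.5, 27.8, 5.3, 20.1, 5.1, 25.7, 5.3))
)

#' Units of the eight MRI parameters
#' @return Named character vector.
#' @export
parameter_units <- function() {
  c(CVR = "beta", CBV = "%", OEF = "", OEC = "", CTH = "s", MTT = "s",
    TTP = "s", CBF = "ml/100g/min")
}

.build_parameter_table <- function() {
  out <- vector("list", 0L)
  for (p in mri_parameters()) {
    for (h in .hemis) {
      v <- .param_values[[p]][[if (h == "ipsi") "ipsi" else "contra"]]
      k <- 0L
      for (g in c("ICAS", "HC")) {
        for (tz in seq_len(4L)) {
          k <- k + 1L
          out[[length(out) + 1L]] <- data.frame(
            parameter = p,
            tissue = .tissue_zone$tissue[tz],
            zone = .tissue_zone$zone[tz],
            hemisphere = h,
            group = g,
            mean = v[2L * k - 1L],
            sd = v[2L * k],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Default group parameter table and clinical fixture
#'
#' Returns the built-in group-statistics fixture for the eight hemodynamic,
#' oxygenation and microvascular MRI parameters: per (parameter, tissue, zone,
#' hemisphere, group) cell, the group mean and standard deviation of the VOI
#' mean, for ICAS patients and healthy controls (HC). The attached clinical
#' fixture carries group-level clinical/cognitive distributions (blood
#' pressure, medication prevalences, NASCET grade, TMT-A/B, MMSE, BDI, STAI)
#' plus the severe/mild patient-subgroup cognition statistics used by the
#' severity model.
#'
#' @return A list of class `icas_fixture` with elements `parameters`
#'   (data frame, 128 rows: 8 parameters x 2 tissues x 2 zones x
#'   2 hemispheres x 2 groups) and `clinical` (list of data frames `group`,
#'   `subgroup`, `medications`).
#' @examples
#' tab <- load_default_parameter_table()
#' subset(tab$parameters, parameter == "CBF" & tissue == "GM" &
#'   zone == "inside" & hemisphere == "ipsi" & group == "ICAS")
#' @export
load_default_parameter_table <- function() {
  params <- .build_parameter_table()
  key <- with(params, paste(parameter, tissue, zone, hemisphere, group))
  if (nrow(params) != 128L || anyDuplicated(key) > 0L)
    stop("corrupted parameter fixture: expected 128 unique entries, got ",
         nrow(params))
  if (any(params$sd < 0))
    stop("corrupted parameter fixture: negative SD")
  pos <- params$parameter %in% c("TTP", "MTT", "CTH", "CBV")
  if (any(params$mean[pos] <= 0))
    stop("corrupted parameter fixture: non-positive timing/volume mean")
  structure(list(parameters = params, clinical = .clinical_fixture()),
            class = "icas_fixture")
}

# Clinical / cognitive distributions -----------------------------------------

# Group-level statistics. NASCET and cognition of patients are drawn from the
# severity subgroups (below); the group marginal emerges as their mixture
# (e.g. TMT-B (17*152.5 + 5*94.4)/22 = 139.3, the printed patient mean).
.clinical_fixture <- function() {
  group <- data.frame(
    measure = c("age", "systolic_bp", "diastolic_bp",
                "tmt_a", "tmt_b", "mmse", "bdi", "stai"),
    icas_mean = c(70.6, 154.3, 85.6, 45.8, 139.3, 28.3, 10.2, 38.9),
    icas_sd   = c(6.4,  23.4,  10.0, 15.1, 64.5,  1.9,  10.7, 11.5),
    hc_mean   = c(70.4, 140.8, 84.2, 48.6, 118.5, 28.8, 7.8,  32.8),
    hc_sd     = c(4.6,  21.5,  7.5,  32.9, 68.9,  1.4,  4.9,  8.2),
    lower     = c(0, 0, 0, 0, 0, 0, 0, 20),
    upper     = c(Inf, Inf, Inf, Inf, Inf, 30, Inf, 80),
    stringsAsFactors = FALSE)
  # Severe = patients the classifier identifies reliably (worse cognition,
  # higher stenosis grade); mild = the frequently misclassified minority.
  subgroup <- data.frame(
    measure = c("tmt_a", "tmt_b", "mmse", "nascet"),
    severe_mean = c(46.6, 152.5, 28.1, 82.6),
    severe_sd   = c(16.7, 66.9,  2.0,  8.3),
    mild_mean   = c(43.4, 94.4,  29.3, 76.0),
    mild_sd     = c(8.7,  26.1,  1.2,  5.5),
    lower       = c(0, 0, 0, 70),
    upper       = c(Inf, Inf, 30, 99),
    stringsAsFactors = FALSE)
  medications <- data.frame(
    drug = c("antiplatelet", "statin", "antihypertensive"),
    icas_prev = c(23, 16, 18) / 24,
    hc_prev = c(6, 5, 9) / 24,
    stringsAsFactors = FALSE)
  list(group = group, subgroup = subgroup, medications = medications,
       stenosis_right_prev = 16 / 24)
}

#' Default per-parameter map exclusion counts
#'
#' Number of subjects whose maps of a given parameter are excluded for low
#' quality, out of `n_subjects`. The reference counts are for a 48-subject
#' cohort (CVR 14; TTP, MTT, OEC, CBV, CTH 7 each; CBF, OEF 5 each, i.e.
#' 59/384 subject-by-parameter entries, about 15%); other cohort sizes are
#' scaled proportionally.
#'
#' @param n_subjects Total cohort size.
#' @return Named integer vector over the eight parameters.
#' @export
default_missingness_counts <- function(n_subjects = 48L) {
  base <- c(CVR = 14, CBV = 7, OEF = 5, OEC = 7, CTH = 7, MTT = 7,
            TTP = 7, CBF = 5)
  counts <- round(base * n_subjects / 48)
  storage.mode(counts) <- "integer"
  counts[mri_parameters()]
}
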
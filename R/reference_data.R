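# Published reference estimates bundled for arithmetic cross-checks.
#
# These tables transcribe the headline results of a published summary-level
# MR study of digestive-system diseases, metabolic mediators and
# cerebrovascular outcomes (GERD = gastroesophageal reflux disease;
# AS/AIS/LAS = any / any ischemic / large-artery atherosclerotic stroke;
# IA/uIA = (unruptured) intracranial aneurysm; SAH = subarachnoid
# hemorrhage; SBP = systolic blood pressure; BMI = body mass index;
# T2D = type 2 diabetes). They carry no genotype-level information: only
# reported odds ratios, p-values and mediation coefficients, used to verify
# that this package's reporting arithmetic (log-OR rounding, Bonferroni
# threshold, significance classification, mediation products) reproduces
# the published numbers.

#' Published screen estimates (reference)
#'
#' Positive two-sample MR results of the reference study: method, SNP
#' count, p-value, odds ratio with 95% CI, heterogeneity (Cochran's Q) and
#' Egger-intercept p-values ("NA" where a column could not be computed at
#' that SNP count).
#'
#' @return data.frame, one row per exposure-outcome pair.
#' @export
tsmr_reference <- function() {
  df <- utils::read.delim(text = "
exposure\toutcome\tmethod\tn_snp\tpval\tor\tci_low\tci_high\tq_pval\tegger_pval
AP\tAS\twald_ratio\t1\t7.971e-5\t0.810\t0.729\t0.899\tNA\tNA
Cholecystitis\tAS\tivw\t2\t3.416e-2\t0.908\t0.831\t0.993\t0.100\tNA
GERD\tAS\tivw\t66\t1.171e-6\t1.232\t1.133\t1.340\t0.068\t0.641
PBC\tAS\tivw\t33\t2.332e-2\t1.021\t1.003\t1.039\t0.126\t0.213
AP\tAIS\twald_ratio\t1\t4.831e-5\t0.788\t0.703\t0.884\tNA\tNA
Cholecystitis\tAIS\tivw\t2\t1.219e-2\t0.892\t0.816\t0.975\t0.134\tNA
GERD\tAIS\tivw\t66\t3.031e-5\t1.210\t1.106\t1.323\t0.116\t0.822
PBC\tAIS\tivw\t33\t1.352e-2\t1.025\t1.005\t1.045\t0.103\t0.275
PBC\tCES\tivw\t33\t3.969e-2\t1.041\t1.002\t1.082\t0.073\t0.354
AP\tLAS\twald_ratio\t1\t1.152e-4\t0.545\t0.401\t0.742\tNA\tNA
Celiac\tLAS\tivw\t34\t2.580e-2\t1.076\t1.009\t1.148\t0.001\t0.859
GERD\tLAS\tivw\t66\t8.576e-5\t1.579\t1.257\t1.984\t0.062\t0.881
NAFLD\tLAS\tivw\t2\t2.867e-3\t0.750\t0.621\t0.906\t0.526\tNA
GERD\tIA\tivw\t56\t2.975e-6\t1.824\t1.418\t2.348\t0.001\t0.424
GERD\tuIA\tivw\t56\t5.485e-4\t2.029\t1.358\t3.030\t0.038\t0.380
CP\tSAH\twald_ratio\t1\t4.755e-2\t0.780\t0.610\t0.997\tNA\tNA
GERD\tSAH\tivw\t56\t1.123e-5\t1.785\t1.378\t2.312\t0.087\t0.086
", stringsAsFactors = FALSE)
  df
}

#' Published mediation coefficients (reference)
#'
#' The reference study's mediation rows for GERD acting through SBP, BMI
#' and T2D on cerebrovascular outcomes: total effect `beta1`,
#' exposure-to-mediator `beta2`, mediator-to-outcome `beta3`, and the
#' published mediated effect (3 dp) and mediating ratio (2 dp).
#'
#' One row (GERD-BMI-AIS) is published with `beta3 = 0.195`, which is
#' inconsistent with the row's own published product (0.043 requires
#' beta3 >= 0.196 at 3 dp) and with the corresponding mediator-to-outcome
#' odds ratio (ln 1.216 = 0.196 at 3 dp); the `beta3` column carries the
#' OR-consistent 0.196 with `beta3_corrected = TRUE`, and the value as
#' published is kept in `beta3_printed`.
#'
#' @return data.frame, one row per exposure-mediator-outcome triplet.
#' @export
mediation_reference <- function() {
  df <- utils::read.delim(text = "
exposure\tmediator\toutcome\tbeta1\tbeta2\tbeta3\tbeta3_printed\tbeta3_corrected\teffect_published\tratio_published_pct
GERD\tSBP\tAS\t0.209\t0.084\t0.554\t0.554\tFALSE\t0.047\t22.49
GERD\tSBP\tAIS\t0.191\t0.084\t0.569\t0.569\tFALSE\t0.048\t25.13
GERD\tSBP\tLAS\t0.457\t0.084\t1.039\t1.039\tFALSE\t0.087\t19.04
GERD\tSBP\tIA\t0.601\t0.084\t1.212\t1.212\tFALSE\t0.102\t16.97
GERD\tSBP\tuIA\t0.707\t0.084\t1.169\t1.169\tFALSE\t0.098\t13.86
GERD\tSBP\tSAH\t0.580\t0.084\t1.361\t1.361\tFALSE\t0.114\t19.66
GERD\tBMI\tAS\t0.209\t0.217\t0.188\t0.188\tFALSE\t0.041\t19.62
GERD\tBMI\tAIS\t0.191\t0.217\t0.196\t0.195\tTRUE\t0.043\t22.51
GERD\tBMI\tLAS\t0.457\t0.217\t0.357\t0.357\tFALSE\t0.077\t16.85
GERD\tBMI\tIA\t0.601\t0.217\t0.303\t0.303\tFALSE\t0.066\t10.98
GERD\tBMI\tSAH\t0.580\t0.217\t0.255\t0.255\tFALSE\t0.055\t9.48
GERD\tT2D\tAS\t0.209\t0.523\t0.083\t0.083\tFALSE\t0.043\t20.57
GERD\tT2D\tAIS\t0.191\t0.523\t0.087\t0.087\tFALSE\t0.046\t24.08
GERD\tT2D\tLAS\t0.457\t0.523\t0.198\t0.198\tFALSE\t0.104\t22.76
", stringsAsFactors = FALSE)
  df
}
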
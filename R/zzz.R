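#' @import data.table
#' @importFrom stats rnorm runif sd cor pt qt
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

## data.table non-standard evaluation column names
utils::globalVariables(c(
  ".", ".N", ".SD", "L", "G", "subject_id", "timepoint", "subfield",
  "volume_mm3", "baseline", "cum", "delta", "k", "module", "t_a", "t_b",
  "nmol_l", "log_nmol", "offset_min", "actual_min", "c_state", "c0", "dc",
  "dh", "log_cort", "cortisol_pg_mg", "cortisone_pg_mg",
  "cortisol_pg_mg_a", "cortisol_pg_mg_b", "cortisone_pg_mg_a",
  "cortisone_pg_mg_b", "day", "car", "slope", "aucg", "measure", "value",
  "value_a", "value_b", "parcel", "netfc", "cohort", "age", "sex", "arm",
  "drop", "gone", "p", "q", "d_cortisol", "d_cortisone", "d_cort",
  "d_brain", "t", "modules"))
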
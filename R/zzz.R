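.datatable.aware <- TRUE

#' @importFrom Rcpp sourceCpp
#' @useDynLib synthehr, .registration = TRUE
NULL

utils::globalVariables(c(".", "row", "vidx", "age", "code"))
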
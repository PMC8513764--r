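#' @keywords internal
#' @importFrom ape as.phylo
#' @importFrom stats reorder
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  register_metric("rf", function(t1, t2) rf_distance(t1, t2))
}

#' @export
ape::as.phylo
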
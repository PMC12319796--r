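# The default constants are pinned by two published anchor points of the
# infinite-k extraction ceiling; refuse to load if they drift.
.onLoad <- function(libname, pkgname) {
  cst <- oef_constants()
  ok <- abs(limit_extraction(21.8, cst) - 0.60) <= 0.01 &&
    abs(limit_extraction(25, cst) - 0.50) <= 0.01
  if (!ok)
    stop("default oxygen-binding constants fail the extraction-ceiling ",
         "anchor checks (0.60 at 21.8 mmHg, 0.50 at 25 mmHg)")
  invisible()
}
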
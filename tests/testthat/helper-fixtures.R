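# Shared fixture assembly. Everything is built in code; the SBML/TSV files
# under inst/extdata mirror toy_network() and are cross-checked in the IO
# tests.

toy_setup <- function() {
  model <- toy_network()
  work <- apply_scenario(model, toy_scenario())
  list(model = model, work = work, decomp = decompose(work),
       expected = attr(model, "expected"))
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "cbfba")
  if (path == "") path <- file.path("../../inst/extdata", name)
  path
}
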
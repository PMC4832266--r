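## The partitioned simulation experiments are expensive; several
## acceptance checks share them, so cache one run per (md, mgr) cell.
.expCache <- new.env(parent = emptyenv())

cachedExperiment <- function(md, mgr) {
  key <- sprintf("md%s_mgr%s", md, mgr)
  if (is.null(.expCache[[key]])) {
    cfg <- simulationConfig(md = md, mgr = mgr, seed = 1L)
    .expCache[[key]] <- suppressWarnings(runPartitionedExperiment(cfg))
  }
  .expCache[[key]]
}
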
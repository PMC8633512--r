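# Shared simulated panels, built once per test run. The small panel backs
# the per-module tests; the full panel (default study conditions: 30 triads,
# divergence 0.08, capture tau 0.04) backs the end-to-end recovery suite.

.panelCache <- new.env(parent = emptyenv())

.buildPanel <- function(cfg) {
  ref <- buildReferenceGenome(cfg)
  sim <- simulatePanel(ref, cfg)
  probes <- designBaits(simGenome(sim), simTargets(sim), simRepeats(sim),
                        min_identity = cfg$screen$min_identity,
                        min_aln_len = cfg$screen$min_aln_len)
  capture <- simulateCapture(sim, probes, tau = 0.04)
  outdir <- file.path(tempdir(), paste0("promcap_panel_", cfg$seed))
  unlink(outdir, recursive = TRUE)
  writePanel(sim, capture, outdir)
  motifs <- system.file("extdata", "plant_motifs_example.tsv",
                        package = "promcap")
  report <- runPipeline(list(
    genome = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "annotation.gff3"),
    targets_tsv = file.path(outdir, "targets.tsv"),
    accessions_tsv = file.path(outdir, "accessions.tsv"),
    vcf_dir = outdir, depth_dir = outdir,
    repeats = file.path(outdir, "repeats.fa"),
    motifs = motifs))
  list(cfg = cfg, ref = ref, sim = sim, probes = probes,
       capture = capture, outdir = outdir, report = report)
}

smallPanel <- function() {
  if (is.null(.panelCache$small)) {
    .panelCache$small <- .buildPanel(
      panelSimConfig(seed = 42, n_homoeo_groups = 6,
                     n_commercial = 4, n_landrace = 4))
  }
  .panelCache$small
}

fullPanel <- function() {
  if (is.null(.panelCache$full)) {
    .panelCache$full <- .buildPanel(panelSimConfig(seed = 1))
  }
  .panelCache$full
}

hexaploidIds <- function(p) {
  acc <- simAccessions(p$sim)
  acc$accession_id[lengths(strsplit(acc$composition, ",")) == 6]
}
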
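#!/usr/bin/env Rscript

# Thin command-line wrapper over peerforum::run_pipeline(). With no
# --corpus the synthetic generator supplies the data.
#
# Example:
#   Rscript scripts/peerforum.R --out run1 --seed 7
#   Rscript scripts/peerforum.R --out run2 --corpus posts.jsonl \
#     --attributes attrs.tsv --taxonomy tax.csv --lexicon liwc.dic

suppressMessages({
  library(optparse)
  library(peerforum)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "peerforum-out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--corpus", type = "character", default = NULL),
  make_option("--attributes", type = "character", default = NULL),
  make_option("--taxonomy", type = "character", default = NULL),
  make_option("--lexicon", type = "character", default = NULL),
  make_option("--patterns", type = "character", default = NULL),
  make_option("--min-wc", type = "integer", default = 25L, dest = "min_wc"),
  make_option("--rq2-min", type = "integer", default = 4L, dest = "rq2_min"),
  make_option("--rq3-min", type = "integer", default = 8L, dest = "rq3_min"),
  make_option("--stages", type = "character",
              default = "synth,mine,classify,score,aggregate,analyze,report")
)))

cfg <- run_config(
  out_dir = opt$out, corpus = opt$corpus, attributes = opt$attributes,
  taxonomy = opt$taxonomy, lexicon = opt$lexicon, patterns = opt$patterns,
  min_wc = opt$min_wc, rq2_min = opt$rq2_min, rq3_min = opt$rq3_min,
  seed = opt$seed, stages = strsplit(opt$stages, ",")[[1]]
)
invisible(run_pipeline(cfg))
cat("report bundle written to", opt$out, "\n")
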
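# shared settings for the analysis workflow; every script sources this
library(eigenlipid)

SEED <- 1L
DATA_DIR <- "results/data"
OUT <- function(...) {
  p <- file.path("results", ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

study_config <- function() ocean_config(seed = SEED)

# read the simulated cruise data written by 01_simulate.R
load_study_data <- function() {
  features <- read_feature_table(file.path(DATA_DIR, "features.tsv"))
  blanks_df <- utils::read.delim(file.path(DATA_DIR, "blanks.tsv"),
                                 check.names = FALSE)
  blanks <- as.matrix(blanks_df[, -1]); rownames(blanks) <- blanks_df[[1]]
  metadata <- utils::read.delim(file.path(DATA_DIR, "metadata.tsv"),
                                stringsAsFactors = FALSE)
  species <- utils::read.delim(file.path(DATA_DIR, "species.tsv"),
                               stringsAsFactors = FALSE)
  list(features = features, blanks = blanks, metadata = metadata,
       species = species)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
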
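# Shared synthetic corpus: 3 classes x 10 records x 6 minutes x 2 leads at
# 250 Hz, default noise, fixed seeds.  Built lazily once per test run and
# reused by the feature-separation and classification tests.

.corpus_cache <- new.env(parent = emptyenv())

corpus_conditions <- c(normal = "normal", ischemia = "ischemia_st_elev",
                       infarction = "infarction")

corpus_records_per_class <- 10L
corpus_minutes_per_record <- 6L

make_corpus_record <- function(condition, i) {
  ci <- match(condition, corpus_conditions)
  r <- generate_record(condition, minutes = corpus_minutes_per_record,
                       n_leads = 2, fs = 250, hr_mean = 70,
                       seed = 10000L * ci + i)
  r <- add_noise(r, noise_params(), seed = 20000L * ci + i)
  r$record_id <- sprintf("%s_%02d", condition, i)
  r
}

corpus_features <- function() {
  if (!is.null(.corpus_cache$features)) return(.corpus_cache$features)
  recs <- list()
  for (cond in corpus_conditions) {
    for (i in seq_len(corpus_records_per_class)) {
      recs[[length(recs) + 1L]] <- make_corpus_record(cond, i)
    }
  }
  pp <- lapply(recs, preprocess_record)
  ft <- extract_dataset(pp, tfd_config())
  .corpus_cache$features <- ft
  ft
}

# record-stratified 80/20 split of the corpus: 2 test records per class
corpus_split <- function(ft = corpus_features()) {
  recs <- unique(as.data.frame(ft)[, c("record_id", "label")])
  test_ids <- unlist(lapply(split(recs$record_id, recs$label),
                            function(ids) sort(ids)[1:2]))
  list(train = feature_table(ft[!(ft$record_id %in% test_ids), ]),
       test = feature_table(ft[ft$record_id %in% test_ids, ]))
}

# probe grid over the feature plane, as feature-table rows
expand_probe_grid <- function(step = 5) {
  g <- expand.grid(p_st = seq(0, 80, by = step), p_pr = seq(0, 80, by = step))
  data.frame(record_id = "probe", segment_index = seq_len(nrow(g)) - 1L,
             lead_name = "I", p_st = g$p_st, p_pr = g$p_pr,
             label = NA_character_)
}

# small well-separated 2-d blob feature table for classifier unit tests
blob_features <- function(n_per = 20, classes = c("normal", "ischemia"),
                          centers = list(c(10, 30), c(40, 10), c(70, 40)),
                          sd = 1, lead = "I", seed = 42,
                          records_per_class = 4) {
  set.seed(seed)
  rows <- NULL
  for (ci in seq_along(classes)) {
    mu <- centers[[ci]]
    rows <- rbind(rows, data.frame(
      record_id = sprintf("%s_r%d", classes[ci],
                          rep_len(seq_len(records_per_class), n_per)),
      segment_index = seq_len(n_per) - 1L,
      lead_name = lead,
      p_st = pmax(0, rnorm(n_per, mu[1], sd)),
      p_pr = pmax(0, rnorm(n_per, mu[2], sd)),
      label = classes[ci]))
  }
  feature_table(rows)
}
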
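# Example pipeline configuration for `soclisten` (study-default criteria).
out_dir: soclisten_run
salt: replace-with-a-secret-salt
token_length: 10
fraction: 0.5
seed: 20180301
cessation_mode: substring
criteria:
  seed_term: sublocade
  max_distance: 1
  context_subreddits: [sublocade]
  window_start: "2018-03-01"
  window_end: "2022-08-31"
  match_mode: substring_list
synthetic:
  n_authors: 1100
  p_target_subreddit: 0.976
  p_term_mention: 0.95
  p_cessation_keyword: 0.9
  p_cessation_construct: 0.438
  p_withdrawal_given_cessation: 0.087
  p_retrospective_given_cessation: 0.828
  n_duplicates: 25
  seed: 20180301
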
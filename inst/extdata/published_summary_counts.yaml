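# Published descriptive counts of the study's Reddit and Twitter corpora
# (corpus sizes, topic frequencies, single/multi-topic distribution, user,
# hashtag and subreddit counts). These integers are inputs to the
# internal-consistency and rounding-convention checks; the raw corpora
# themselves are not redistributable.
reddit:
  "N": 40625
  unique_users: 18891
  mean_posts_per_user_printed: 2.12
  posts_with_hyperlinks: 1793
  total_hyperlinks: 3698
  comments: 38633
  submissions: 1992
  unique_subreddits: 2534
  top_subreddit:
    name: CrohnsDisease
    count: 10529
  at_least_one_topic: 32189
  no_topic: 8436
  topics:
    symptoms: 23294
    medication: 12218
    nutrition: 11039
    procedures: 6798
    marijuana: 3352
    stigma: 1482
    ostomy: 1346
    intimacy: 930
  exactly_1: 13705
  exactly_2: 11134
  three_plus: 7350
  multitopic_network_N: 18484
twitter:
  "N": 40306
  unique_users: 20665
  mean_posts_per_user_printed: 1.95
  posts_with_hyperlinks: 10177
  total_hyperlinks: 14325
  total_hashtags: 51065
  unique_hashtags: 9043
  tweets_with_hashtags: 12363
  mean_hashtags_per_post_printed: 1.27
  at_least_one_topic: 22398
  no_topic: 17908
  topics:
    symptoms: 14488
    medication: 4515
    nutrition: 3675
    procedures: 2220
    marijuana: 1912
    stigma: 1250
    ostomy: 1179
    intimacy: 141
  exactly_1: 16258
  exactly_2: 5360
  three_plus: 780
  multitopic_network_N: 6140
# printed percentage labels for the topic table, used to validate the
# half-up / "<1%" rounding convention
topic_pct_printed:
  reddit:
    symptoms: "57%"
    medication: "30%"
    nutrition: "27%"
    procedures: "17%"
    marijuana: "8%"
    stigma: "4%"
    ostomy: "3%"
    intimacy: "2%"
  twitter:
    symptoms: "36%"
    medication: "11%"
    nutrition: "9%"
    procedures: "6%"
    marijuana: "5%"
    stigma: "3%"
    ostomy: "3%"
    intimacy: "<1%"
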
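name: "Horne-Ostberg Morningness-Eveningness Questionnaire (1976 scoring)"
version: "1.0"
# 19 items; per-item minima sum to 16, maxima to 86.
# kind: time_scale items carry a midpoint (decimal hours) per option;
# clock times after midnight are offset past 24 (01:30 -> 25.5) so cohort
# means of preferred bed times stay on a continuous scale.
items:
  - index: 1
    kind: time_scale
    text: "Approximately what time would you get up if you were entirely free to plan your day?"
    options:
      - {label: "05:00-06:30", score: 5, mid: 5.75}
      - {label: "06:30-07:45", score: 4, mid: 7.125}
      - {label: "07:45-09:45", score: 3, mid: 8.75}
      - {label: "09:45-11:00", score: 2, mid: 10.375}
      - {label: "11:00-12:00", score: 1, mid: 11.5}
  - index: 2
    kind: time_scale
    text: "Approximately what time would you go to bed if you were entirely free to plan your evening?"
    options:
      - {label: "20:00-21:00", score: 5, mid: 20.5}
      - {label: "21:00-22:15", score: 4, mid: 21.625}
      - {label: "22:15-00:30", score: 3, mid: 23.375}
      - {label: "00:30-01:45", score: 2, mid: 25.125}
      - {label: "01:45-03:00", score: 1, mid: 26.375}
  - index: 3
    kind: choice
    text: "If you usually have to get up at a specific time in the morning, how much do you depend on an alarm clock?"
    options:
      - {label: "Not at all dependent", score: 4}
      - {label: "Slightly dependent", score: 3}
      - {label: "Fairly dependent", score: 2}
      - {label: "Very dependent", score: 1}
  - index: 4
    kind: choice
    text: "How easy do you find getting up in the morning?"
    options:
      - {label: "Not at all easy", score: 1}
      - {label: "Not very easy", score: 2}
      - {label: "Fairly easy", score: 3}
      - {label: "Very easy", score: 4}
  - index: 5
    kind: choice
    text: "How alert do you feel during the first half hour after waking?"
    options:
      - {label: "Not at all alert", score: 1}
      - {label: "Slightly alert", score: 2}
      - {label: "Fairly alert", score: 3}
      - {label: "Very alert", score: 4}
  - index: 6
    kind: choice
    text: "How is your appetite during the first half hour after waking?"
    options:
      - {label: "Very poor", score: 1}
      - {label: "Fairly poor", score: 2}
      - {label: "Fairly good", score: 3}
      - {label: "Very good", score: 4}
  - index: 7
    kind: choice
    text: "During the first half hour after waking, how tired do you feel?"
    options:
      - {label: "Very tired", score: 1}
      - {label: "Fairly tired", score: 2}
      - {label: "Fairly refreshed", score: 3}
      - {label: "Very refreshed", score: 4}
  - index: 8
    kind: choice
    text: "When you have no commitments the next day, at what time do you go to bed compared with your usual bedtime?"
    options:
      - {label: "Seldom or never later", score: 4}
      - {label: "Less than one hour later", score: 3}
      - {label: "One to two hours later", score: 2}
      - {label: "More than two hours later", score: 1}
  - index: 9
    kind: choice
    text: "You have decided to take physical exercise with a friend between 07:00 and 08:00. How do you think you would perform?"
    options:
      - {label: "Would be in good form", score: 4}
      - {label: "Would be in reasonable form", score: 3}
      - {label: "Would find it difficult", score: 2}
      - {label: "Would find it very difficult", score: 1}
  - index: 10
    kind: time_scale
    text: "At what time in the evening do you feel tired and in need of sleep?"
    options:
      - {label: "20:00-21:00", score: 5, mid: 20.5}
      - {label: "21:00-22:15", score: 4, mid: 21.625}
      - {label: "22:15-00:45", score: 3, mid: 23.5}
      - {label: "00:45-02:00", score: 2, mid: 25.375}
      - {label: "02:00-03:00", score: 1, mid: 26.5}
  - index: 11
    kind: choice
    text: "At what time of day would you choose to sit a two-hour test you know will be mentally exhausting?"
    options:
      - {label: "08:00-10:00", score: 6}
      - {label: "11:00-13:00", score: 4}
      - {label: "15:00-17:00", score: 2}
      - {label: "19:00-21:00", score: 0}
  - index: 12
    kind: choice
    text: "If you went to bed at 23:00, how tired would you be?"
    options:
      - {label: "Not at all tired", score: 0}
      - {label: "A little tired", score: 2}
      - {label: "Fairly tired", score: 3}
      - {label: "Very tired", score: 5}
  - index: 13
    kind: choice
    text: "You have gone to bed several hours later than usual, but need not get up at any particular time. Which are you most likely to do?"
    options:
      - {label: "Wake at the usual time and not fall asleep again", score: 4}
      - {label: "Wake at the usual time and doze thereafter", score: 3}
      - {label: "Wake at the usual time but fall asleep again", score: 2}
      - {label: "Not wake until later than usual", score: 1}
  - index: 14
    kind: choice
    text: "You must stay awake between 04:00 and 06:00 for a night watch, with no commitments the next day. Which alternative suits you best?"
    options:
      - {label: "Not go to bed until the watch is over", score: 1}
      - {label: "Take a nap before and sleep after", score: 2}
      - {label: "Take a good sleep before and nap after", score: 3}
      - {label: "Take all sleep before the watch", score: 4}
  - index: 15
    kind: choice
    text: "You have two hours of hard physical work and are entirely free to plan your day. At what time would you choose to do it?"
    options:
      - {label: "08:00-10:00", score: 4}
      - {label: "11:00-13:00", score: 3}
      - {label: "15:00-17:00", score: 2}
      - {label: "19:00-21:00", score: 1}
  - index: 16
    kind: choice
    text: "You have decided to take hard physical exercise between 22:00 and 23:00 with a friend. How well do you think you would perform?"
    options:
      - {label: "Would be in good form", score: 1}
      - {label: "Would be in reasonable form", score: 2}
      - {label: "Would find it difficult", score: 3}
      - {label: "Would find it very difficult", score: 4}
  - index: 17
    kind: time_scale
    text: "Suppose you can choose your own work hours for a rewarding five-hour day. At what time would you start?"
    options:
      - {label: "Starting 04:00-08:00", score: 5, mid: 6.0}
      - {label: "Starting 08:00-09:00", score: 4, mid: 8.5}
      - {label: "Starting 09:00-14:00", score: 3, mid: 11.5}
      - {label: "Starting 14:00-17:00", score: 2, mid: 15.5}
      - {label: "Starting 17:00-04:00", score: 1, mid: 22.5}
  - index: 18
    kind: time_scale
    text: "At what time of day do you think you reach your feeling-best peak?"
    options:
      - {label: "05:00-08:00", score: 5, mid: 6.5}
      - {label: "08:00-10:00", score: 4, mid: 9.0}
      - {label: "10:00-17:00", score: 3, mid: 13.5}
      - {label: "17:00-22:00", score: 2, mid: 19.5}
      - {label: "22:00-05:00", score: 1, mid: 25.5}
  - index: 19
    kind: choice
    text: "One hears about morning and evening types of people. Which type do you consider yourself to be?"
    options:
      - {label: "Definitely a morning type", score: 6}
      - {label: "Rather more a morning than an evening type", score: 4}
      - {label: "Rather more an evening than a morning type", score: 2}
      - {label: "Definitely an evening type", score: 0}
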
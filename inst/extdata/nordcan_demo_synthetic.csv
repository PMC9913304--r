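"country","sex","site","period","horizon","estimate","ci_low","ci_high","design"
"DK","male","colon","1971-1975","1y",60.1,58.5,61.6,"cohort"
"DK","male","colon","1976-1980","1y",61.2,59.6,62.7,"cohort"
"DK","male","colon","1981-1985","1y",62.2,60.7,63.8,"cohort"
"DK","male","colon","1986-1990","1y",63.8,62.3,65.4,"cohort"
"DK","male","colon","1991-1995","1y",69.1,67.5,70.6,"cohort"
"DK","male","colon","1996-2000","1y",71.8,70.3,73.4,"cohort"
"DK","male","colon","2001-2005","1y",76.8,75.2,78.3,"cohort"
"DK","male","colon","2006-2010","1y",80.6,79.1,82.2,"cohort"
"DK","male","colon","2011-2015","1y",82.3,80.7,83.8,"cohort"
"DK","male","colon","2016-2020","1y",83.3,81.7,84.9,"hybrid"
"DK","male","colon","1971-1975","5y",36.3,34.7,37.9,"cohort"
"DK","male","colon","1976-1980","5y",35.8,34.2,37.3,"cohort"
"DK","male","colon","1981-1985","5y",37,35.4,38.5,"cohort"
"DK","male","colon","1986-1990","5y",40.5,39,42.1,"cohort"
"DK","male","colon","1991-1995","5y",45.1,43.5,46.6,"cohort"
"DK","male","colon","1996-2000","5y",50.1,48.5,51.7,"cohort"
"DK","male","colon","2001-2005","5y",56.4,54.8,58,"cohort"
"DK","male","colon","2006-2010","5y",61.6,60,63.2,"cohort"
"DK","male","colon","2011-2015","5y",65.4,63.8,66.9,"cohort"
"DK","male","colon","2016-2020","5y",67.4,65.8,69,"hybrid"
"DK","female","colon","1971-1975","1y",62,60.4,63.6,"cohort"
"DK","female","colon","1976-1980","1y",62.9,61.3,64.4,"cohort"
"DK","female","colon","1981-1985","1y",65.1,63.6,66.7,"cohort"
"DK","female","colon","1986-1990","1y",67,65.4,68.6,"cohort"
"DK","female","colon","1991-1995","1y",71.5,69.9,73.1,"cohort"
"DK","female","colon","1996-2000","1y",74.4,72.8,76,"cohort"
"DK","female","colon","2001-2005","1y",78.7,77.2,80.3,"cohort"
"DK","female","colon","2006-2010","1y",82.4,80.9,84,"cohort"
"DK","female","colon","2011-2015","1y",84.3,82.8,85.9,"cohort"
"DK","female","colon","2016-2020","1y",84,82.5,85.6,"hybrid"
"DK","female","colon","1971-1975","5y",37,35.5,38.6,"cohort"
"DK","female","colon","1976-1980","5y",38.3,36.7,39.9,"cohort"
"DK","female","colon","1981-1985","5y",39.5,37.9,41,"cohort"
"DK","female","colon","1986-1990","5y",42.9,41.3,44.4,"cohort"
"DK","female","colon","1991-1995","5y",48.1,46.5,49.6,"cohort"
"DK","female","colon","1996-2000","5y",53.5,51.9,55.1,"cohort"
"DK","female","colon","2001-2005","5y",61.6,60,63.2,"cohort"
"DK","female","colon","2006-2010","5y",65.4,63.9,67,"cohort"
"DK","female","colon","2011-2015","5y",67.8,66.2,69.4,"cohort"
"DK","female","colon","2016-2020","5y",70.9,69.3,72.4,"hybrid"
"DK","male","rectum","1971-1975","1y",58.5,56.9,60,"cohort"
"DK","male","rectum","1976-1980","1y",59.6,58.1,61.2,"cohort"
"DK","male","rectum","1981-1985","1y",60.7,59.1,62.2,"cohort"
"DK","male","rectum","1986-1990","1y",62.8,61.3,64.4,"cohort"
"DK","male","rectum","1991-1995","1y",66.7,65.2,68.3,"cohort"
"DK","male","rectum","1996-2000","1y",69,67.4,70.5,"cohort"
"DK","male","rectum","2001-2005","1y",75.2,73.6,76.8,"cohort"
"DK","male","rectum","2006-2010","1y",79.2,77.6,80.7,"cohort"
"DK","male","rectum","2011-2015","1y",80.6,79.1,82.2,"cohort"
"DK","male","rectum","2016-2020","1y",83.2,81.6,84.8,"hybrid"
"DK","male","rectum","1971-1975","5y",33.3,31.8,34.9,"cohort"
"DK","male","rectum","1976-1980","5y",33.2,31.6,34.7,"cohort"
"DK","male","rectum","1981-1985","5y",35.2,33.6,36.8,"cohort"
"DK","male","rectum","1986-1990","5y",37.7,36.1,39.3,"cohort"
"DK","male","rectum","1991-1995","5y",43.1,41.6,44.7,"cohort"
"DK","male","rectum","1996-2000","5y",47.4,45.8,49,"cohort"
"DK","male","rectum","2001-2005","5y",54.9,53.4,56.5,"cohort"
"DK","male","rectum","2006-2010","5y",60.7,59.2,62.3,"cohort"
"DK","male","rectum","2011-2015","5y",62.6,61,64.1,"cohort"
"DK","male","rectum","2016-2020","5y",65.2,63.7,66.8,"hybrid"
"DK","female","rectum","1971-1975","1y",61.4,59.8,62.9,"cohort"
"DK","female","rectum","1976-1980","1y",60.4,58.8,61.9,"cohort"
"DK","female","rectum","1981-1985","1y",61.9,60.3,63.5,"cohort"
"DK","female","rectum","1986-1990","1y",63.8,62.2,65.4,"cohort"
"DK","female","rectum","1991-1995","1y",68.2,66.7,69.8,"cohort"
"DK","female","rectum","1996-2000","1y",70.6,69,72.1,"cohort"
"DK","female","rectum","2001-2005","1y",76.2,74.6,77.8,"cohort"
"DK","female","rectum","2006-2010","1y",80.4,78.8,81.9,"cohort"
"DK","female","rectum","2011-2015","1y",82.6,81,84.2,"cohort"
"DK","female","rectum","2016-2020","1y",83.2,81.6,84.8,"hybrid"
"DK","female","rectum","1971-1975","5y",35.2,33.6,36.8,"cohort"
"DK","female","rectum","1976-1980","5y",36.3,34.7,37.8,"cohort"
"DK","female","rectum","1981-1985","5y",37.1,35.5,38.6,"cohort"
"DK","female","rectum","1986-1990","5y",40.2,38.7,41.8,"cohort"
"DK","female","rectum","1991-1995","5y",45.1,43.5,46.7,"cohort"
"DK","female","rectum","1996-2000","5y",51.7,50.1,53.3,"cohort"
"DK","female","rectum","2001-2005","5y",57.8,56.3,59.4,"cohort"
"DK","female","rectum","2006-2010","5y",63.7,62.1,65.3,"cohort"
"DK","female","rectum","2011-2015","5y",65.1,63.5,66.7,"cohort"
"DK","female","rectum","2016-2020","5y",70,68.4,71.6,"hybrid"
"DK","male","small_intestine","1971-1975","1y",50.3,46.4,54.2,"cohort"
"DK","male","small_intestine","1976-1980","1y",51.6,47.7,55.5,"cohort"
"DK","male","small_intestine","1981-1985","1y",51.3,47.4,55.2,"cohort"
"DK","male","small_intestine","1986-1990","1y",55.9,51.9,59.8,"cohort"
"DK","male","small_intestine","1991-1995","1y",57.4,53.5,61.3,"cohort"
"DK","male","small_intestine","1996-2000","1y",62.5,58.6,66.4,"cohort"
"DK","male","small_intestine","2001-2005","1y",66.5,62.6,70.4,"cohort"
"DK","male","small_intestine","2006-2010","1y",70.3,66.4,74.2,"cohort"
"DK","male","small_intestine","2011-2015","1y",76.2,72.3,80.1,"cohort"
"DK","male","small_intestine","2016-2020","1y",69.4,65.5,73.4,"hybrid"
"DK","male","small_intestine","1971-1975","5y",27.3,23.4,31.2,"cohort"
"DK","male","small_intestine","1976-1980","5y",26.6,22.7,30.5,"cohort"
"DK","male","small_intestine","1981-1985","5y",27.3,23.4,31.2,"cohort"
"DK","male","small_intestine","1986-1990","5y",29,25.1,32.9,"cohort"
"DK","male","small_intestine","1991-1995","5y",34.9,31,38.8,"cohort"
"DK","male","small_intestine","1996-2000","5y",42.8,38.9,46.7,"cohort"
"DK","male","small_intestine","2001-2005","5y",46.7,42.7,50.6,"cohort"
"DK","male","small_intestine","2006-2010","5y",48.2,44.3,52.1,"cohort"
"DK","male","small_intestine","2011-2015","5y",54,50.1,57.9,"cohort"
"DK","male","small_intestine","2016-2020","5y",59.2,55.3,63.1,"hybrid"
"DK","female","small_intestine","1971-1975","1y",53.1,49.2,57,"cohort"
"DK","female","small_intestine","1976-1980","1y",55.3,51.4,59.2,"cohort"
"DK","female","small_intestine","1981-1985","1y",57.4,53.4,61.3,"cohort"
"DK","female","small_intestine","1986-1990","1y",58.8,54.9,62.7,"cohort"
"DK","female","small_intestine","1991-1995","1y",64.8,60.9,68.7,"cohort"
"DK","female","small_intestine","1996-2000","1y",67.5,63.6,71.4,"cohort"
"DK","female","small_intestine","2001-2005","1y",68.2,64.2,72.1,"cohort"
"DK","female","small_intestine","2006-2010","1y",74.8,70.9,78.7,"cohort"
"DK","female","small_intestine","2011-2015","1y",75.1,71.1,79,"cohort"
"DK","female","small_intestine","2016-2020","1y",77.3,73.4,81.2,"hybrid"
"DK","female","small_intestine","1971-1975","5y",27.5,23.6,31.4,"cohort"
"DK","female","small_intestine","1976-1980","5y",30.4,26.5,34.3,"cohort"
"DK","female","small_intestine","1981-1985","5y",30.2,26.3,34.1,"cohort"
"DK","female","small_intestine","1986-1990","5y",35,31.1,38.9,"cohort"
"DK","female","small_intestine","1991-1995","5y",37.2,33.3,41.1,"cohort"
"DK","female","small_intestine","1996-2000","5y",39.2,35.3,43.1,"cohort"
"DK","female","small_intestine","2001-2005","5y",49.5,45.6,53.4,"cohort"
"DK","female","small_intestine","2006-2010","5y",54.7,50.8,58.7,"cohort"
"DK","female","small_intestine","2011-2015","5y",60.3,56.4,64.2,"cohort"
"DK","female","small_intestine","2016-2020","5y",60.8,56.8,64.7,"hybrid"
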
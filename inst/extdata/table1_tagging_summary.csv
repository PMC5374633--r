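# Tagging summary for 20 DTAG deployments on short-finned pilot whales off
# Cape Hatteras, North Carolina: deployment date, tag id, tag on/off times
# (local), total record time (hh:mm), biopsy taken, sex (M/F/U, - = no
# biopsy), total dives analysed, and the number of dives allocated to each
# of the four behavioural states.
# Note: tag 209a's printed total time (01:09) differs from its on/off times
# (which imply 01:15); the printed value is kept.
date,tag_id,time_on,time_off,total_time,biopsy,sex,total_dives,state1,state2,state3,state4
22-May-08,143a,14:28,17:41,03:13,N,-,4,2,2,0,0
22-May-08,143b,18:18,22:38,04:20,N,-,9,3,0,6,0
26-May-08,147a,15:02,17:20,02:18,N,-,7,7,0,0,0
30-May-08,151a,08:46,09:51,01:05,N,-,3,1,1,1,0
30-May-08,151b,13:14,05:56,16:42,N,-,17,9,1,7,0
04-Jul-10,185b,14:30,20:18,05:48,Y,F,5,1,3,1,0
05-Jul-10,186a,11:10,11:36,00:26,N,-,2,2,0,0,0
05-Jul-10,186b,14:32,16:28,01:56,Y,F,3,3,0,0,0
06-Jul-10,187b,12:53,06:07,17:14,Y,M,34,2,18,13,1
27-Jul-10,208a,14:50,23:30,08:40,Y,F,34,9,0,25,0
28-Jul-10,209a,08:54,10:09,01:09,Y,M,3,0,1,2,0
28-Jul-10,209c,13:19,19:45,06:26,Y,M,4,1,0,3,0
23-Sep-10,266a,18:35,12:49,18:14,N,-,32,3,11,4,14
24-Sep-10,267a,15:19,09:03,17:44,Y,M,64,7,1,43,13
29-May-11,149b,10:33,14:52,04:18,Y,M,7,1,6,0,0
30-May-11,150b,11:11,13:51,02:39,N,-,7,2,4,1,0
05-Jun-11,156a,12:11,15:07,02:55,N,-,3,0,0,3,0
14-Jun-11,165a,09:25,12:34,03:08,Y,M,9,0,7,2,0
07-Oct-14,279a,12:42,15:51,03:10,Y,U,10,5,2,0,3
08-Oct-14,280a,12:31,15:12,02:41,Y,U,2,1,0,1,0
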